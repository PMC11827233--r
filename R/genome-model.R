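# Domain types for structures, populations, annotations and nucleus geometry,
# plus readers/writers for the tabular formats the pipeline touches.
# Conventions: genomic intervals are 0-based half-open (BED); coordinates are
# in nm; homolog copies are 0/1 and kept separate throughout clustering.

#' Nucleus geometry
#'
#' Describes the confining nuclear envelope: a sphere of radius `R_nuc` or an
#' ellipsoid with semiaxes `(a, b, c)`, all in nm.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param R_nuc Nuclear radius in nm (sphere only).
#' @param semiaxes Numeric length-3 vector of semiaxes in nm (ellipsoid only).
#' @return An object of class `nucleus_geometry`.
#' @examples
#' nucleus_geometry("sphere", R_nuc = 5000)
#' @export
nucleus_geometry <- function(shape = c("sphere", "ellipsoid"), R_nuc = NULL,
                             semiaxes = NULL) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    if (is.null(R_nuc) || !is.null(semiaxes))
      stop("sphere geometry takes exactly R_nuc")
    if (!is.numeric(R_nuc) || length(R_nuc) != 1L || R_nuc <= 0)
      stop("R_nuc must be a positive length")
    g <- list(shape = shape, R_nuc = as.numeric(R_nuc))
  } else {
    if (is.null(semiaxes) || !is.null(R_nuc))
      stop("ellipsoid geometry takes exactly semiaxes")
    if (length(semiaxes) != 3L || any(semiaxes <= 0))
      stop("semiaxes must be three positive lengths")
    g <- list(shape = shape, semiaxes = as.numeric(semiaxes))
  }
  structure(g, class = "nucleus_geometry")
}

#' Per-bin annotation track
#'
#' Fixed-width bin annotation for one or more chromosomes: bead category
#' (`"domain"` beads enter the analysis, `"cen"` beads -- centromeric or
#' telomeric -- are removed) and optional Hi-C subcompartment labels.
#'
#' @param chrom Chromosome identifier per bin.
#' @param start,end 0-based half-open interval in bp; constant width except
#'   possibly the last bin of a chromosome.
#' @param category `"domain"` or `"cen"`.
#' @param subcompartment Optional: one of `"A1","A2","B1","B2","B3"` or `NA`.
#' @return A `data.frame` of class `bin_annotation` with a `bin_width`
#'   attribute.
#' @export
bin_annotation <- function(chrom, start, end, category = "domain",
                           subcompartment = NA_character_) {
  ann <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), category = as.character(category),
                    subcompartment = as.character(subcompartment),
                    stringsAsFactors = FALSE)
  if (!all(ann$category %in% c("domain", "cen")))
    stop("category must be 'domain' or 'cen'")
  bad <- !(ann$subcompartment %in% c("A1", "A2", "B1", "B2", "B3") |
             is.na(ann$subcompartment))
  if (any(bad)) stop("unknown subcompartment label")
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    if (is.unsorted(a$start, strictly = TRUE))
      stop("bins must be sorted within chromosome ", ch)
    if (any(a$start[-1] != a$end[-nrow(a)]))
      stop("bins must be contiguous within chromosome ", ch)
  }
  w <- ann$end - ann$start
  attr(ann, "bin_width") <- as.numeric(stats::median(w))
  class(ann) <- c("bin_annotation", "data.frame")
  ann
}

#' Single chromosome-copy structure
#'
#' Ordered 3D bead coordinates (nm) of one chromosome copy of one cell. Beads
#' are spheres of radius `R_bead` (default 118 nm, giving a genome-to-nucleus
#' volume ratio of 0.4 at 200-kb resolution).
#'
#' @param structure_id Identifier of the originating cell/structure.
#' @param chrom Chromosome identifier.
#' @param copy Homolog copy, 0 or 1.
#' @param coords Numeric n x 3 matrix of bead centers in nm.
#' @param R_bead Bead radius in nm.
#' @return Object of class `chrom_structure`.
#' @export
chrom_structure <- function(structure_id, chrom, copy, coords, R_bead = 118) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (R_bead <= 0) stop("R_bead must be positive")
  if (!copy %in% c(0L, 1L)) stop("copy must be 0 or 1")
  structure(list(structure_id = structure_id, chrom = as.character(chrom),
                 copy = as.integer(copy), coords = unname(coords),
                 R_bead = as.numeric(R_bead)),
            class = "chrom_structure")
}

#' @export
print.chrom_structure <- function(x, ...) {
  cat(sprintf("<chrom_structure %s %s copy %d: %d beads, R_bead %g nm>\n",
              x$structure_id, x$chrom, x$copy, nrow(x$coords), x$R_bead))
  invisible(x)
}

n_beads <- function(s) nrow(s$coords)

#' Diploid genome structure population
#'
#' A collection of whole-genome diploid coordinate sets sharing one bead
#' table (chrom / copy / bin), one nucleus geometry, and one bin annotation.
#'
#' @param structures Named list; each element an N x 3 coordinate matrix (nm)
#'   with identical bead ordering.
#' @param bead_table `data.frame` with columns `chrom`, `copy`, `start`,
#'   `end`, one row per bead, defining that ordering.
#' @param geometry A [nucleus_geometry()].
#' @param annotation Optional [bin_annotation()] covering the bins.
#' @param R_bead Bead radius in nm.
#' @param strict If `TRUE`, a bead further than `R_bead` outside the nuclear
#'   envelope is an error; otherwise a warning (models may graze the
#'   envelope).
#' @return Object of class `genome_population`.
#' @export
genome_population <- function(structures, bead_table, geometry,
                              annotation = NULL, R_bead = 118,
                              strict = FALSE) {
  if (is.null(names(structures)))
    names(structures) <- as.character(seq_along(structures))
  nb <- nrow(bead_table)
  for (nm in names(structures)) {
    x <- structures[[nm]]
    if (!is.matrix(x) || ncol(x) != 3L)
      stop("structure ", nm, ": coordinates must be an N x 3 matrix")
    if (nrow(x) != nb)
      stop("structure ", nm, ": bead count ", nrow(x),
           " does not match bead table (", nb, ")")
  }
  pop <- structure(list(structures = structures, bead_table = bead_table,
                        geometry = geometry, annotation = annotation,
                        R_bead = as.numeric(R_bead)),
                   class = "genome_population")
  check_containment(pop, strict = strict)
  pop
}

#' @export
print.genome_population <- function(x, ...) {
  cat(sprintf("<genome_population: %d structures x %d beads (%s nucleus)>\n",
              length(x$structures), nrow(x$bead_table), x$geometry$shape))
  invisible(x)
}

# Normalized radial position of points for a geometry (1 = at the envelope).
radial_positions <- function(coords, geometry) {
  if (geometry$shape == "sphere") {
    sqrt(rowSums(coords^2)) / geometry$R_nuc
  } else {
    s <- geometry$semiaxes
    sqrt((coords[, 1] / s[1])^2 + (coords[, 2] / s[2])^2 +
           (coords[, 3] / s[3])^2)
  }
}

# Containment check with tolerance of one bead radius beyond the envelope.
check_containment <- function(pop, strict = FALSE) {
  g <- pop$geometry
  lim <- if (g$shape == "sphere") {
    (g$R_nuc + pop$R_bead) / g$R_nuc
  } else {
    1 + pop$R_bead / min(g$semiaxes)
  }
  for (nm in names(pop$structures)) {
    r <- radial_positions(pop$structures[[nm]], g)
    if (any(r > lim)) {
      msg <- sprintf(
        "structure %s: %d bead(s) outside the nucleus by more than R_bead",
        nm, sum(r > lim))
      if (strict) stop(msg) else warning(msg)
    }
  }
  invisible(pop)
}

#' Extract all copies of one chromosome from a population
#'
#' Isolates individual chromosome copies from each whole-genome structure;
#' for an autosome this yields two structures per cell.
#'
#' @param pop A [genome_population()].
#' @param chrom Chromosome identifier present in the bead table.
#' @return List of [chrom_structure()] objects (cells x copies).
#' @export
extract_chromosome_copies <- function(pop, chrom) {
  bt <- pop$bead_table
  if (!chrom %in% bt$chrom) stop("unknown chromosome: ", chrom)
  copies <- sort(unique(bt$copy[bt$chrom == chrom]))
  out <- list()
  for (nm in names(pop$structures)) {
    for (cp in copies) {
      sel <- bt$chrom == chrom & bt$copy == cp
      out[[length(out) + 1L]] <- chrom_structure(
        structure_id = nm, chrom = chrom, copy = cp,
        coords = pop$structures[[nm]][sel, , drop = FALSE],
        R_bead = pop$R_bead)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Coordinate-table I/O. TSV with columns structure_id, chrom, copy,
# bin_start, x, y, z (nm); 0-based bin starts; bead order within a structure
# is (chrom in order of first appearance, copy, bin_start).

#' Write a population to a coordinate table
#' @param pop A [genome_population()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  bt <- pop$bead_table
  tabs <- lapply(names(pop$structures), function(nm) {
    data.table::data.table(structure_id = nm, chrom = bt$chrom,
                           copy = bt$copy, bin_start = bt$start,
                           x = pop$structures[[nm]][, 1],
                           y = pop$structures[[nm]][, 2],
                           z = pop$structures[[nm]][, 3])
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t")
  invisible(path)
}

#' Read a population of diploid genome structures
#'
#' @param path Coordinate table path (TSV; columns `structure_id`, `chrom`,
#'   `copy`, `bin_start`, `x`, `y`, `z`).
#' @param format Only `"coord-table"` is supported by this build; the
#'   `"hdf5-population"` layout is recognised but not implemented.
#' @param geometry A [nucleus_geometry()] for the containment check.
#' @param annotation Optional [bin_annotation()]; its bin width is used for
#'   bead intervals, otherwise inferred from consecutive bin starts.
#' @param R_bead Bead radius in nm.
#' @param strict Containment violations beyond one bead radius are an error
#'   when `TRUE`, a warning otherwise.
#' @return A [genome_population()].
#' @export
read_population <- function(path, format = c("coord-table", "hdf5-population"),
                            geometry, annotation = NULL, R_bead = 118,
                            strict = FALSE) {
  format <- match.arg(format)
  if (format == "hdf5-population")
    stop("hdf5-population input is not supported by this build; ",
         "use the coord-table format")
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c(1, 2)))
  need <- c("structure_id", "chrom", "copy", "bin_start", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("coord-table must have columns ", paste(need, collapse = ", "))
  for (cl in c("copy", "bin_start", "x", "y", "z")) {
    v <- dt[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("parse error in column '", cl, "' near line ", bad + 1L)
    }
  }
  ids <- unique(dt$structure_id)
  first <- dt[dt$structure_id == ids[1], ]
  nb <- nrow(first)
  width <- if (!is.null(annotation)) attr(annotation, "bin_width") else {
    ds <- diff(sort(unique(first$bin_start)))
    if (length(ds)) min(ds) else 2e5
  }
  bead_table <- data.frame(chrom = first$chrom, copy = as.integer(first$copy),
                           start = as.numeric(first$bin_start),
                           end = as.numeric(first$bin_start) + width,
                           stringsAsFactors = FALSE)
  structures <- lapply(ids, function(id) {
    d <- dt[dt$structure_id == id, ]
    if (nrow(d) != nb)
      stop("bead-count mismatch: structure ", id, " has ", nrow(d),
           " beads, expected ", nb)
    if (!identical(d$chrom, first$chrom) ||
        !identical(d$bin_start, first$bin_start))
      stop("bead ordering mismatch in structure ", id)
    unname(cbind(d$x, d$y, d$z))
  })
  names(structures) <- ids
  genome_population(structures, bead_table, geometry, annotation,
                    R_bead = R_bead, strict = strict)
}

# ---------------------------------------------------------------------------
# Chromatin-tracing tables (DNA-MERFISH style).

#' Read a chromatin-tracing table
#'
#' Reads per-copy imaged locus coordinates (nm). Internal missing coordinates
#' are filled by per-axis linear interpolation along genomic position; copies
#' without at least two valid loci (or without valid speckle distances when
#' `require_speckle`) are dropped.
#'
#' @param path TSV with columns `copy_id`, `pos` (bp), `x`, `y`, `z` and
#'   optionally `speckle_dist` (nm) and `trans_on` (counts). Missing values
#'   are `NA`.
#' @param interpolate Fill internal missing coordinates.
#' @param require_speckle Drop copies lacking any valid speckle distance.
#' @return Object of class `tracing_dataset`: list of copies, each with
#'   `copy_id`, `pos`, `coords`, and optional `speckle_dist`, `trans_on`.
#' @export
read_tracing <- function(path, interpolate = TRUE, require_speckle = FALSE) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("copy_id", "pos", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("tracing table must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(dt$copy_id)) {
    d <- as.data.frame(dt[dt$copy_id == id, ])
    d <- d[order(d$pos), ]
    if (any(duplicated(d$pos))) stop("duplicate locus positions in copy ", id)
    cm <- as.matrix(d[, c("x", "y", "z")])
    valid <- rowSums(is.na(cm)) == 0
    if (sum(valid) < 2) {
      warning("copy ", id, " dropped: fewer than 2 valid loci")
      next
    }
    if (require_speckle &&
        (!"speckle_dist" %in% names(d) || all(is.na(d$speckle_dist)))) {
      warning("copy ", id, " dropped: no valid speckle distance")
      next
    }
    if (interpolate && any(!valid)) {
      for (ax in 1:3)
        cm[, ax] <- approx(d$pos[valid], cm[valid, ax], xout = d$pos,
                           rule = 1)$y
    }
    keep <- rowSums(is.na(cm)) == 0
    cp <- list(copy_id = id, pos = d$pos[keep],
               coords = unname(cm[keep, , drop = FALSE]))
    if ("speckle_dist" %in% names(d)) cp$speckle_dist <- d$speckle_dist[keep]
    if ("trans_on" %in% names(d)) cp$trans_on <- d$trans_on[keep]
    out[[length(out) + 1L]] <- cp
  }
  structure(list(copies = out), class = "tracing_dataset")
}

# ---------------------------------------------------------------------------
# Per-bin tracks as bedGraph (0-based half-open intervals at bin width).

#' Write a per-bin track as bedGraph
#'
#' @param track Numeric vector, one value per bin; `NA` bins are omitted.
#' @param chrom Chromosome identifier.
#' @param path Output path.
#' @param bin_width Bin width in bp.
#' @param offset Start of the first bin in bp.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(track, chrom, path, bin_width = 2e5, offset = 0,
                           name = "track") {
  starts <- offset + (seq_along(track) - 1) * bin_width
  lines <- sprintf("track type=bedGraph name=\"%s\"", name)
  keep <- !is.na(track)
  if (any(keep))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.10g", chrom,
                              as.integer(starts[keep]),
                              as.integer(starts[keep] + bin_width),
                              track[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track back into a per-bin vector
#'
#' Inverse of [write_profiles()]: bins absent from the file become `NA`.
#'
#' @param path bedGraph path.
#' @param n_bins Number of bins of the target vector.
#' @param bin_width Bin width in bp.
#' @param offset Start of the first bin in bp.
#' @return Numeric vector of length `n_bins`.
#' @export
read_profiles <- function(path, n_bins, bin_width = 2e5, offset = 0) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- rep(NA_real_, n_bins)
  if (length(gr)) {
    idx <- (GenomicRanges::start(gr) - 1 - offset) / bin_width + 1
    track[round(idx)] <- GenomicRanges::score(gr)
  }
  track
}

#' Read a BED-style bin category / subcompartment file
#'
#' Columns: chrom, start, end, name; the name field carries either the bead
#' category (`domain`/`cen`) or a subcompartment label.
#'
#' @param path BED path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = gr$name, stringsAsFactors = FALSE)
}

# Dense matrices as (optionally gzipped) TSV.

#' @rdname read_matrix
#' @param m Matrix to write.
#' @export
write_matrix <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Dense matrix I/O as (gzipped) TSV
#' @param path File path; `.gz` suffix enables compression.
#' @return `read_matrix`: a numeric matrix.
#' @export
read_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  unname(as.matrix(utils::read.table(con, sep = "\t", header = FALSE)))
}
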
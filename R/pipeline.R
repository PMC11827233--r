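# End-to-end workflows binding the modules together, plus thin command
# entry points with run manifests. Desk-scale defaults (grid 500, minimum
# cluster size 30, autoencoder input resized to side 100, perplexity 50)
# keep a full run within minutes on a laptop; `paper_scale = TRUE` restores
# the full-scale constants (grid 1000, minimum cluster size 100, perplexity
# 200, native resize target).

#' Run the full clustering pipeline on a set of chromosome structures
#'
#' filter -> surface distance matrices -> max-normalize -> resize ->
#' autoencoder -> latent standardization -> t-SNE -> outlier removal ->
#' KDE -> peak detection -> watershed assignment -> silhouette.
#'
#' @param structures List of [chrom_structure()] objects; alternatively
#'   pass `matrices` directly.
#' @param matrices Optional list of max-normalized distance matrices
#'   (values in `[0, 1]`), bypassing the structure-to-matrix step. They are
#'   still resized to `resize_side`.
#' @param annotation Optional [bin_annotation()]; when given, `"cen"` beads
#'   are removed first.
#' @param spec An [autoencoder_spec()].
#' @param resize_side Autoencoder input side (multiple of 50). The
#'   desk-scale default 100 is the smallest side at which the
#'   three-pooling-stage architecture retains a spatially resolved latent
#'   (2 x 2 x 4); `NULL` resizes each matrix to its nearest multiple of 50.
#' @param perplexity,learning_rate t-SNE parameters. The desk default
#'   perplexity 50 scales the full-run value (200 at 20,000 structures)
#'   to desk-sized inputs; `paper_scale` restores 200.
#' @param grid_size KDE grid side.
#' @param min_cluster_size Minimum watershed cluster size.
#' @param nlevels Watershed density levels.
#' @param paper_scale Use the full-scale constants (grid 1000, min size
#'   100, perplexity 200, native resize).
#' @param seed Master seed (autoencoder training, t-SNE initialization).
#' @return List of class `cluster_run`: `embedding`, `kept` (indices of
#'   points surviving outlier removal), `grid`, `peaks`, `assignment`,
#'   `labels` (per input structure, `NA` for outliers/unclustered),
#'   `silhouette`, `model`, `matrices` (resized inputs), `seed`.
#' @export
cluster_pipeline <- function(structures = NULL, matrices = NULL,
                             annotation = NULL,
                             spec = autoencoder_spec(), resize_side = 100,
                             perplexity = 50, learning_rate = 1000,
                             grid_size = 500, min_cluster_size = 30,
                             nlevels = 100, paper_scale = FALSE, seed = 1L) {
  if (paper_scale) {
    grid_size <- 1000; min_cluster_size <- 100; resize_side <- NULL
    perplexity <- 200
  }
  if (is.null(matrices)) {
    if (!is.null(annotation))
      structures <- lapply(structures, filter_beads, ann = annotation)
    mats <- lapply(structures, embedding_input_matrix, side = resize_side)
  } else {
    mats <- lapply(matrices, resize_to_multiple_of_50, side = resize_side)
  }
  model <- train_autoencoder(mats, spec, seed = seed)
  lat <- standardize_latents(encode(model, mats))
  emb <- tsne_embed(lat, perplexity = perplexity,
                    learning_rate = learning_rate, seed = seed)
  ol <- remove_outliers(emb)
  grid <- kde_density(ol$points, gridsize = grid_size, seed = seed)
  peaks <- detect_peaks(grid)
  assignment <- watershed_assign(grid, peaks, ol$points,
                                 min_size = min_cluster_size,
                                 nlevels = nlevels)
  labels <- rep(NA_integer_, nrow(emb))
  labels[ol$kept] <- assignment$labels
  sil <- if (length(assignment$sizes) >= 2)
    silhouette_score(ol$points, assignment$labels) else NULL
  structure(list(embedding = emb, kept = ol$kept, grid = grid,
                 peaks = peaks, assignment = assignment, labels = labels,
                 silhouette = sil, model = model, matrices = mats,
                 seed = as.integer(seed)),
            class = "cluster_run")
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf("<cluster_run: %d structures -> %d clusters%s>\n",
              length(x$labels), length(x$assignment$sizes),
              if (!is.null(x$silhouette))
                sprintf(", mean silhouette %.2f", x$silhouette$mean) else ""))
  invisible(x)
}

#' Per-cluster feature profiles
#'
#' Computes, for every cluster and for the ensemble of all clustered
#' structures: contact and average distance matrices, the distance-variant
#' insulation profile and called boundaries, radius-of-gyration and radial
#' tracks, and the log2 cluster-vs-ensemble ratio tracks.
#'
#' @param structures The structures that were clustered (same order as
#'   `labels`).
#' @param labels Integer labels with `NA` for unclustered structures.
#' @param geometry Optional [nucleus_geometry()] for radial tracks.
#' @param coarse_window,fine_window Boundary-calling windows in bins.
#' @param binarize_threshold Distance-insulation threshold.
#' @return Named list of per-cluster profiles plus `ensemble`; each profile
#'   has `CM`, `DM`, `insulation`, `boundaries`, `rg`, and (with geometry)
#'   `rad`, plus `rg_ratio`/`rad_ratio` against the ensemble.
#' @export
cluster_profiles <- function(structures, labels, geometry = NULL,
                             coarse_window = NULL, fine_window = NULL,
                             binarize_threshold = 0.45) {
  keep <- which(!is.na(labels))
  if (!length(keep)) stop("no clustered structures")
  n <- n_beads(structures[[1]])
  if (is.null(coarse_window)) coarse_window <- max(10, min(200, n %/% 4))
  if (is.null(fine_window)) fine_window <- max(5, min(30, coarse_window %/% 3))
  profile_of <- function(set) {
    CM <- cluster_contact_matrix(set)
    DM <- average_distance_matrix(set)
    ins <- insulation_profile(DM, "distance", fine_window, binarize_threshold)
    bnd <- call_boundaries(DM, coarse_window, fine_window, binarize_threshold)
    rg <- rowMeans(vapply(set, rg_profile, numeric(n)))
    out <- list(CM = CM, DM = DM, insulation = ins, boundaries = bnd,
                rg = rg, n_structures = length(set))
    if (!is.null(geometry)) out$rad <- radial_track(set, geometry)
    out
  }
  ens <- profile_of(structures[keep])
  out <- list()
  for (k in sort(unique(labels[keep]))) {
    p <- profile_of(structures[which(labels == k)])
    p$rg_ratio <- log2_ratio_track(p$rg, ens$rg)
    if (!is.null(geometry)) p$rad_ratio <- log2_ratio_track(p$rad, ens$rad)
    out[[as.character(k)]] <- p
  }
  out$ensemble <- ens
  out
}

write_manifest <- function(config, outdir, extra = list()) {
  man <- c(list(package = "chromomorph",
                version = as.character(utils::packageVersion("chromomorph")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = config), extra)
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate synthetic fixture datasets on disk
#'
#' Runs the synthetic-data generators for a configuration and writes
#' coordinate tables (positive and negative controls), the truth labels and
#' a run manifest.
#'
#' @param config Named list: any [simulation_config()] arguments plus
#'   `outdir` and optionally `n_negative`.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config = list()) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_args <- config[intersect(names(config),
                               names(formals(simulation_config)))]
  cfg <- do.call(simulation_config, cfg_args)
  pos <- positive_control(cfg,
                          noise_space = config$noise_space %||% "matrix")
  write_structure_table(control_structures(pos, cfg),
                        file.path(outdir, "positive_control.tsv"))
  neg <- negative_control(cfg, n_structures = config$n_negative %||% 100)
  write_structure_table(neg, file.path(outdir, "negative_control.tsv"))
  write_manifest(config, outdir,
                 list(truth = list(labels = pos$labels, sigmas = pos$sigmas),
                      seed = cfg$seed))
  invisible(outdir)
}

#' Cluster a structure table from disk
#'
#' Reads a per-chromosome-copy coordinate table, runs [cluster_pipeline()]
#' and writes the assignment table, peak list and silhouette report.
#'
#' @param config Named list: `input` (structure table), `outdir`, `seed`,
#'   plus any [cluster_pipeline()] arguments.
#' @return The `cluster_run`, invisibly.
#' @export
cmd_cluster <- function(config = list()) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  structures <- read_structure_table(config$input %||%
                                       stop("config$input is required"))
  args <- config[intersect(names(config), names(formals(cluster_pipeline)))]
  run <- do.call(cluster_pipeline, c(list(structures = structures), args))
  ids <- vapply(structures, function(s) s$structure_id, "")
  cps <- vapply(structures, function(s) s$copy, 0L)
  utils::write.table(
    data.frame(structure_id = ids, copy = cps, cluster = run$labels),
    file.path(outdir, "assignments.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(peaks = run$assignment$peaks, sizes = run$assignment$sizes,
         occupancy = run$assignment$occupancy,
         silhouette = run$silhouette[c("mean", "by_cluster")],
         seed = run$seed),
    file.path(outdir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(config[setdiff(names(config), "input")], outdir,
                 list(input = config$input, seed = run$seed))
  invisible(run)
}

#' Compute per-cluster feature profiles from an assignment
#'
#' @param config Named list: `input` (structure table), `assignments`
#'   (TSV from [cmd_cluster()]), `outdir`, optional profile arguments.
#' @return The profile list, invisibly.
#' @export
cmd_features <- function(config = list()) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  structures <- read_structure_table(config$input)
  asg <- utils::read.table(config$assignments, sep = "\t", header = TRUE)
  labels <- asg$cluster
  profs <- cluster_profiles(structures, labels)
  for (k in setdiff(names(profs), "ensemble")) {
    p <- profs[[k]]
    write_matrix(p$CM, file.path(outdir, sprintf("cluster%s_CM.tsv.gz", k)))
    write_matrix(p$DM, file.path(outdir, sprintf("cluster%s_DM.tsv.gz", k)))
    write_profiles(p$insulation, structures[[1]]$chrom,
                   file.path(outdir, sprintf("cluster%s_insulation.bedGraph", k)),
                   name = paste0("insulation_", k))
    doms <- territory_domains(p$boundaries, length(p$insulation))
    utils::write.table(doms, file.path(outdir,
                                       sprintf("cluster%s_domains.tsv", k)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_manifest(config, outdir)
  invisible(profs)
}

#' Classify external single-cell data against cluster references
#'
#' Sci-Hi-C mode (`config$mode = "scihic"`): imputes each raw cell matrix,
#' scores it against cluster masks, and repeats on randomized controls.
#' Tracing mode (`"tracing"`): classifies each copy's distance matrix
#' against cluster average distance matrices by correlation.
#'
#' @param config Named list; see Details in the vignette.
#' @return `data.frame` of per-cell assignments, invisibly.
#' @export
cmd_classify <- function(config = list()) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mode <- config$mode %||% "scihic"
  if (mode == "scihic") {
    cells <- config$cells
    masks <- config$masks
    res <- lapply(seq_along(cells), function(i) {
      bin <- impute_scihic(cells[[i]], w = config$w %||% 5)
      score_scihic(bin, masks, margin = config$margin %||% 0.01)
    })
  } else {
    res <- lapply(config$structures, classify_structure,
                  cluster_dms = config$cluster_dms,
                  margin = config$margin %||% 0.05)
  }
  tab <- data.frame(
    cell = seq_along(res),
    assigned = vapply(res, function(r) r$assigned %||% NA_character_, ""),
    margin = vapply(res, function(r) r$margin, 0))
  utils::write.table(tab, file.path(outdir, "classification.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(config[setdiff(names(config),
                                c("cells", "masks", "structures",
                                  "cluster_dms"))], outdir)
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a table of chromosome-copy structures
#'
#' Same column layout as the population coordinate table; one block per
#' chromosome-copy structure keyed by `structure_id` + `copy`.
#'
#' @param structures List of [chrom_structure()] objects.
#' @param path TSV path.
#' @return `read_structure_table`: list of [chrom_structure()] objects.
#' @export
write_structure_table <- function(structures, path) {
  tabs <- lapply(structures, function(s)
    data.table::data.table(structure_id = s$structure_id, chrom = s$chrom,
                           copy = s$copy,
                           bin_start = (seq_len(n_beads(s)) - 1) * 2e5,
                           x = s$coords[, 1], y = s$coords[, 2],
                           z = s$coords[, 3]))
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t")
  invisible(path)
}

#' @rdname write_structure_table
#' @export
read_structure_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  key <- paste(dt$structure_id, dt$copy)
  lapply(unique(key), function(k) {
    d <- dt[key == k, ]
    chrom_structure(d$structure_id[1], d$chrom[1], d$copy[1],
                    cbind(d$x, d$y, d$z))
  })
}
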
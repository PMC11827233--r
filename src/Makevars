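# -fassociative-math (with its prerequisites) lets the compiler vectorize
# the dot-product reductions in the backward passes; unlike full fast-math
# it preserves inf/NaN semantics.
PKG_CXXFLAGS = -O3 -funroll-loops -fno-math-errno -fno-signed-zeros \
    -fno-trapping-math -fassociative-math -freciprocal-math
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
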
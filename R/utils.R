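# internal helpers shared across modules

# data.table non-standard evaluation symbols
utils::globalVariables(c("gene_a", "gene_b", "score", "p_value", "cis"))

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# strip/keep the "chr" prefix so two interval sources agree on one dialect
normalize_chroms <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# upper-triangle pair indices (i < j) in the order produced by mi_all_pairs_cpp
pair_indices <- function(G) {
  stopifnot(G >= 2)
  list(i = rep.int(seq_len(G - 1L), times = (G - 1L):1L),
       j = sequence((G - 1L):1L, from = 2:G))
}
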
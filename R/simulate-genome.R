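#' Generate a synthetic genome with a controlled GC landscape
#'
#' Bases are drawn independently per position: each base is G or C with the
#' window's target GC probability (A or T otherwise), so the realized GC of
#' any window of at least 10 kb sits within about 0.03 of its target.
#'
#' @param config a [sim_config]; `gc_landscape` is recycled across
#'   `gc_window` windows of every chromosome.
#' @return a [genome_model] with chromosomes `chr1..chrN`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$chrom_length >= config$gc_window,
              "chrom_length smaller than the GC window")
  lens <- rep_len(config$chrom_length, config$n_chrom)
  with_seed(derive_seed(config$seed, "genome"), {
    seqs <- vapply(seq_len(config$n_chrom), function(i) {
      L <- as.integer(lens[i])
      n_win <- ceiling(L / config$gc_window)
      targets <- rep_len(config$gc_landscape, n_win)
      p <- rep(targets, each = config$gc_window)[seq_len(L)]
      is_gc <- runif(L) < p
      pick <- runif(L) < 0.5
      # codes: A=65 T=84 G=71 C=67
      code <- ifelse(is_gc, ifelse(pick, 71L, 67L), ifelse(pick, 65L, 84L))
      rawToChar(as.raw(code))
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(config$n_chrom))
  genome_model(seqs)
}
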
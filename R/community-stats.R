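# Genome relative abundance from mapped-read counts and rank correlation
# against environmental parameters.

#' Reads per kilobase of genome per million mapped reads
#'
#' `mapped / ((genome_len / 1e3) * (total / 1e6))`. The kb/million scaling
#' constants leave all rankings unchanged relative to the unscaled
#' mapped / (length x metagenome size) ratio.
#'
#' @param mapped Mapped-read count(s).
#' @param genome_len Genome length(s) in bp (> 0).
#' @param total Per-sample total read count(s) (> 0); the metagenome size.
#' @return Numeric RPKM value(s); vectorised.
#' @examples
#' rpkm(2000, 2e6, 1e7)  # 0.1
#' @export
rpkm <- function(mapped, genome_len, total) {
  if (any(genome_len <= 0)) stop("genome_len must be positive")
  if (any(total <= 0)) stop("total must be positive")
  mapped / ((genome_len / 1e3) * (total / 1e6))
}

#' Per-sample abundance fractions and RPKM shares
#'
#' For every sample: the raw read fraction `mapped / total` per genome,
#' the RPKM value, and the RPKM-normalised relative share (summing to 1
#' over genomes within each sample with nonzero RPKM; a sample with no
#' mapped reads gets `NA` shares).
#'
#' @param table An [AbundanceTable-class].
#' @return `data.frame` with columns `sample`, `genome`, `mapped`,
#'   `fraction`, `rpkm`, `share`.
#' @export
abundanceFractions <- function(table) {
  counts <- assay(table, "counts")
  lens <- genomeLengths(table)
  totals <- totalReads(table)
  out <- lapply(colnames(counts), function(s) {
    mapped <- counts[, s]
    rk <- rpkm(mapped, lens, totals[[s]])
    denom <- sum(rk)
    data.frame(sample = s, genome = rownames(counts), mapped = mapped,
               fraction = mapped / totals[[s]], rpkm = rk,
               share = if (denom > 0) rk / denom else NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties get the average rank), via
#' [stats::cor.test()]. The p-value uses the t approximation; for small
#' samples a seeded permutation p-value is available.
#'
#' @param x,y Numeric vectors; pairs with a missing value are removed, and
#'   at least 3 complete pairs are required.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation null.
#' @return List with `rho` and `p`.
#' @export
spearmanCorr <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 9999L, seed = NULL) {
  p_method <- match.arg(p_method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rho undefined for a constant vector")
  rho <- unname(cor(x, y, method = "spearman"))
  p <- if (p_method == "t") {
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = FALSE))$p.value
  } else {
    withSeed(seed, {
      null <- replicate(n_perm,
                        abs(cor(x, sample(y), method = "spearman")))
      (sum(null >= abs(rho)) + 1) / (n_perm + 1)
    })
  }
  list(rho = rho, p = unname(p))
}

#' Correlate genome abundance with environmental parameters
#'
#' Spearman correlation of a per-sample abundance vector against each
#' environmental parameter; missing values are removed pairwise, and
#' Benjamini-Hochberg adjusted q-values are reported across parameters.
#'
#' @param abundance Named numeric vector: sample -> abundance (e.g. an
#'   RPKM or fraction column from [abundanceFractions()]).
#' @param env `data.frame` of environmental parameters, rows matched to
#'   samples by rownames.
#' @param p_method,n_perm,seed Passed to [spearmanCorr()].
#' @return `data.frame` with columns `parameter`, `n`, `rho`, `p`, `q`.
#' @export
envCorrelations <- function(abundance, env, p_method = c("t", "permutation"),
                            n_perm = 9999L, seed = NULL) {
  p_method <- match.arg(p_method)
  samples <- intersect(names(abundance), rownames(env))
  if (length(samples) < 3L) stop("fewer than 3 shared samples")
  rows <- lapply(colnames(env), function(par) {
    x <- abundance[samples]
    y <- env[samples, par]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3L || length(unique(y[ok])) == 1L)
      return(data.frame(parameter = par, n = sum(ok), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    sc <- spearmanCorr(x, y, p_method = p_method, n_perm = n_perm,
                       seed = seed)
    data.frame(parameter = par, n = sum(ok), rho = sc$rho, p = sc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
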
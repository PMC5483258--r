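#' Canonical k-mer frequency spectrum of a read set
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and
#' its reverse complement); windows containing non-ACGT characters are
#' skipped.
#'
#' @param reads named character vector, DNAStringSet, or FASTQ path.
#' @param k odd k-mer size, at most 31.
#' @return an object of class `kmer_spectrum`: `k`, `histogram`
#'   (data.frame frequency, n_kmers, ascending), `total_kmer_instances`.
#' @export
count_kmers <- function(reads, k = 21L) {
  if (k %% 2 == 0) stop("k must be odd")
  if (k > 31) stop("k must be at most 31")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  reads <- as_seq_vector(reads)
  short <- nchar(reads) < k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than k skipped")
    reads <- reads[!short]
  }
  r <- cpp_count_kmers(unname(reads), as.integer(k))
  o <- order(r$frequency)
  structure(list(k = k,
                 histogram = data.frame(frequency = r$frequency[o],
                                        n_kmers = r$n_kmers[o]),
                 total_kmer_instances = r$total_instances),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: k =", x$k, ",",
      format(sum(x$histogram$n_kmers), big.mark = ","), "distinct k-mers,",
      format(x$total_kmer_instances, big.mark = ","), "instances\n")
  invisible(x)
}

dense_histogram <- function(spectrum) {
  h <- spectrum$histogram
  fmax <- max(h$frequency)
  dense <- numeric(fmax)
  dense[h$frequency] <- h$n_kmers
  dense
}

## first local minimum of the dense histogram: smallest f with
## h[f] <= h[f+1] (the error/signal valley); 0 when the histogram
## rises from the start.
first_local_min <- function(dense) {
  if (length(dense) < 3) return(0L)
  for (f in seq_len(length(dense) - 1L))
    if (dense[f] <= dense[f + 1L]) return(f)
  0L
}

nb_mix_negll <- function(par, freq, cnt, cutoff, ratio_free) {
  mu1 <- exp(par[1])
  mu2 <- if (ratio_free) exp(par[2]) else 2 * mu1
  size <- exp(par[if (ratio_free) 3 else 2])
  w <- stats::plogis(par[if (ratio_free) 4 else 3])
  pmf <- w * dnbinom(freq, mu = mu1, size = size) +
    (1 - w) * dnbinom(freq, mu = mu2, size = size)
  norm <- 1 - (w * pnbinom(cutoff, mu = mu1, size = size) +
                 (1 - w) * pnbinom(cutoff, mu = mu2, size = size))
  if (!is.finite(norm) || norm <= 1e-12) return(1e12)
  ll <- sum(cnt * (log(pmax(pmf, 1e-300)) - log(norm)))
  -ll
}

#' Fit a diploid two-component mixture to a k-mer spectrum
#'
#' Above the error cutoff (the first local minimum of the histogram),
#' the spectrum is modelled as a mixture of two negative binomial
#' components with means constrained to mu and 2*mu (single-copy
#' heterozygous and two-copy homozygous sequence) and a shared
#' dispersion, fit by maximum likelihood on the truncated
#' distribution.  The genome size estimate divides the above-cutoff
#' k-mer instances by mu, so fully diverged single-copy regions count
#' once per haplotype (a diploid-span convention).  An unconstrained
#' two-mean refit is reported as a diagnostic.
#'
#' @param spectrum a [count_kmers()] result.
#' @param error_cutoff optional override of the detected cutoff.
#' @return an object of class `spectrum_fit`: `mu_het`, `mu_hom`,
#'   `dispersion`, `weight_single` (mixture weight of the single-copy
#'   component among distinct k-mers), `fraction_single_copy` and
#'   `fraction_two_copy` (genome-span fractions),
#'   `genome_size_estimate` (bp), `error_cutoff`, `loglik`,
#'   `single_component` flag, and `unconstrained` (mu1, mu2, ratio).
#' @export
fit_spectrum <- function(spectrum, error_cutoff = NULL) {
  dense <- dense_histogram(spectrum)
  cutoff <- if (is.null(error_cutoff)) first_local_min(dense)
            else as.integer(error_cutoff)
  f <- spectrum$histogram$frequency
  n <- spectrum$histogram$n_kmers
  keep <- f > cutoff
  if (!any(keep)) stop("no histogram mass above the error cutoff")
  f <- f[keep]; n <- n[keep]

  mode_f <- f[which.max(n)]
  fits <- lapply(c(mode_f, max(1, mode_f / 2)), function(mu0) {
    par0 <- c(log(mu0), log(mu0), 0)   # log mu, log size, logit w
    stats::optim(par0, nb_mix_negll, freq = f, cnt = n, cutoff = cutoff,
                 ratio_free = FALSE, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  mu <- exp(fit$par[1]); size <- exp(fit$par[2])
  w <- stats::plogis(fit$par[3])

  D <- sum(n)
  D1 <- w * D; D2 <- (1 - w) * D
  span <- D1 + 2 * D2
  instances <- sum(as.numeric(f) * n)
  genome_size <- instances / mu
  single_component <- w < 0.05 || w > 0.95

  ## unconstrained diagnostic refit
  par0 <- c(log(mu), log(2 * mu), log(size), stats::qlogis(min(max(w, 1e-3),
                                                               1 - 1e-3)))
  ufit <- stats::optim(par0, nb_mix_negll, freq = f, cnt = n, cutoff = cutoff,
                       ratio_free = TRUE, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-10))
  umu <- sort(exp(ufit$par[1:2]))
  structure(list(
    mu_het = mu, mu_hom = 2 * mu, dispersion = size, weight_single = w,
    fraction_single_copy = D1 / span, fraction_two_copy = 2 * D2 / span,
    genome_size_estimate = genome_size, error_cutoff = cutoff,
    loglik = -fit$value, single_component = single_component,
    unconstrained = list(mu1 = umu[1], mu2 = umu[2],
                         ratio = umu[2] / umu[1], loglik = -ufit$value)),
    class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("spectrum fit: peaks at %.1f and %.1f (error cutoff %d)\n",
              x$mu_het, x$mu_hom, x$error_cutoff))
  cat(sprintf("  single copy %.0f%%, two copy %.0f%%, genome size %.2f Mbp\n",
              100 * x$fraction_single_copy, 100 * x$fraction_two_copy,
              x$genome_size_estimate / 1e6))
  if (x$single_component)
    cat("  note: fit is effectively single-component (haploid-like)\n")
  invisible(x)
}
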
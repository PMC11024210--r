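#' Proportion of RG-only clones with a hierarchical bootstrap CI
#'
#' Pools clones at the requested chase timepoint(s) and reports the fraction
#' whose composition is \code{"RG_only"} (clones containing only radial
#' glia, whether one or many cells), with a percentile bootstrap confidence
#' interval that resamples hemispheres first (cluster bootstrap) and then
#' clones within each resampled hemisphere.
#'
#' @param clones data.frame with columns \code{clone_id},
#'   \code{hemisphere_id}, \code{chase_days}, \code{composition}.
#' @param at_days timepoint(s) to include (default: all).
#' @param n_boot bootstrap replicates (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list: \code{proportion}, \code{ci} (length 2), \code{n_clones},
#'   \code{n_hemispheres}, \code{boot} (the replicate proportions).
#' @export
rg_only_proportion <- function(clones, at_days = NULL, n_boot = 10000L,
                               conf = 0.95, seed = 1L) {
  sub <- if (is.null(at_days)) clones
         else clones[clones$chase_days %in% at_days, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no clones at the requested timepoint")
  set.seed(seed)
  is_rg <- sub$composition == "RG_only"
  prop <- mean(is_rg)
  hemis <- split(is_rg, sub$hemisphere_id)
  H <- length(hemis)
  boot <- vapply(seq_len(n_boot), function(b) {
    hs <- sample.int(H, H, replace = TRUE)
    v <- unlist(lapply(hemis[hs], function(x)
      x[sample.int(length(x), length(x), replace = TRUE)]))
    mean(v)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  list(proportion = prop, ci = ci, n_clones = nrow(sub),
       n_hemispheres = H, boot = boot)
}

#' Exact two-sided binomial test by minimum-likelihood summation
#'
#' Direct summation of the binomial probability mass over all outcomes at
#' most as likely as the observed one (with the same relative tolerance
#' factor as the standard exact test), the common convention for a
#' two-sided exact binomial p-value.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @return the p-value.
#' @export
binomial_two_sided <- function(k, n, p0) {
  if (n < 0L || k < 0L || k > n) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  pm <- stats::dbinom(0:n, n, p0)
  obs <- pm[k + 1L]
  min(1, sum(pm[pm <= obs * (1 + 1e-7)]))
}

#' Mann-Whitney U test with Cliff's delta effect size
#'
#' Two-sided Mann-Whitney U (exact null distribution when the samples are
#' tie-free and small, tie-corrected normal approximation otherwise) plus
#' Cliff's delta \eqn{(\#\{x>y\} - \#\{x<y\})/(nm)} with a percentile
#' bootstrap confidence interval. Ties count half in U, so the identity
#' \eqn{\delta = 2U/(nm) - 1} holds exactly.
#'
#' @param x,y numeric vectors (e.g. smFISH dot counts of induced and
#'   control cells).
#' @param n_boot bootstrap replicates for the delta CI (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list: \code{U}, \code{p}, \code{delta}, \code{delta_ci},
#'   \code{n}, \code{m}.
#' @export
mannwhitney_cliffs <- function(x, y, n_boot = 10000L, conf = 0.95,
                               seed = 1L) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both groups must be nonempty")
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2    # ties count half
  ties <- any(duplicated(c(x, y)))
  if (!ties && n * m <= 10000L) {
    p <- min(1, 2 * min(stats::pwilcox(U, n, m),
                        stats::pwilcox(n * m - U, n, m)))
  } else {
    nt <- table(c(x, y))
    tie_term <- sum(nt^3 - nt)
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    p <- if (sigma2 <= 0) 1 else {   # all observations tied
      z <- (U - n * m / 2 - sign(U - n * m / 2) * 0.5) / sqrt(sigma2)
      2 * stats::pnorm(-abs(z))
    }
  }
  delta_of <- function(a, b) {
    ra <- rank(c(a, b), ties.method = "average")
    u <- sum(ra[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    2 * u / (length(a) * length(b)) - 1
  }
  delta <- delta_of(x, y)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b)
    delta_of(x[sample.int(n, n, replace = TRUE)],
             y[sample.int(m, m, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  list(U = U, p = min(p, 1), delta = delta,
       delta_ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n = n, m = m)
}

#' Compare the RG-only clone proportion against a population proportion
#'
#' Assembles the bootstrapped RG-only clone proportion and the exact
#' two-sided binomial test of the observed RG-only count against the
#' population proportion of the deep-quiescent cluster (e.g. the q4 share
#' of radial glia) into one report. A clone proportion far below the
#' population share indicates that the population does contribute to
#' neurogenesis rather than sitting out.
#'
#' @param clones clone table (see \code{\link{rg_only_proportion}}).
#' @param q4_proportion population proportion in (0, 1).
#' @param at_days timepoint(s) to include (default: all).
#' @param n_boot,conf,seed bootstrap settings.
#' @return list of class \code{clone_report}: \code{proportion},
#'   \code{ci}, \code{k}, \code{n}, \code{p0}, \code{p_binomial}.
#' @export
compare_clone_vs_population <- function(clones, q4_proportion,
                                        at_days = NULL, n_boot = 10000L,
                                        conf = 0.95, seed = 1L) {
  if (q4_proportion <= 0 || q4_proportion >= 1)
    stop("q4_proportion must be in (0, 1)")
  rg <- rg_only_proportion(clones, at_days = at_days, n_boot = n_boot,
                           conf = conf, seed = seed)
  k <- round(rg$proportion * rg$n_clones)
  p <- binomial_two_sided(k, rg$n_clones, q4_proportion)
  structure(list(proportion = rg$proportion, ci = rg$ci, k = k,
                 n = rg$n_clones, p0 = q4_proportion, p_binomial = p),
            class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf(
    "RG-only clones: %d/%d (%.1f%%), bootstrap CI [%.1f%%, %.1f%%]\n",
    x$k, x$n, 100 * x$proportion, 100 * x$ci[1], 100 * x$ci[2]))
  cat(sprintf("two-sided binomial test vs population share %.0f%%: p = %.3g\n",
              100 * x$p0, x$p_binomial))
  invisible(x)
}
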
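# Per-fragment CNV calling: a two-component Gaussian mixture separates a
# null subdistribution (fragments at equal dosage, log2 ratio near 0) from a
# variant subdistribution (fragments whose dosage differs). A fragment is
# called when its posterior probability of belonging to the variant
# component exceeds p_min AND its absolute log2 ratio exceeds min_abs_log2
# (a near two-fold signal change); the call direction follows the sign.

#' Fit a two-component Gaussian mixture by expectation maximization
#'
#' One fit per genotype over all its fragment signals. The variant component
#' is the one whose mean lies farther from 0 (ties broken by larger
#' variance); it is two-sided — call direction comes from the ratio's sign,
#' not from separate components. Initialization is deterministic: the null
#' component starts at (median, MAD^2) and the variant component at the mean
#' of the values beyond 0.9 in absolute value (falling back to the most
#' extreme 5%), with inflated variance.
#'
#' @param values Numeric vector of fragment log2 ratios for one genotype.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `cnv_mixture`: `pi` (variant mixing proportion),
#'   `mu_variant`, `sigma_variant`, `mu_null`, `sigma_null`, `posterior`
#'   (per-observation P(variant), in input order), `loglik` (trace),
#'   `n_iter`, `converged`.
#' @export
fit_two_component_em <- function(values, tol = 1e-8, max_iter = 500) {
  if (!all(is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < 2 || stats::sd(values) == 0) {
    warning("degenerate input: null-only fit, all posteriors 0")
    return(structure(list(pi = 0, mu_variant = NA_real_,
                          sigma_variant = NA_real_,
                          mu_null = mean(values),
                          sigma_null = 0,
                          posterior = rep(0, n), loglik = numeric(0),
                          n_iter = 0L, converged = TRUE),
                     class = "cnv_mixture"))
  }
  mu0 <- stats::median(values)
  s0 <- stats::mad(values)
  if (s0 == 0) s0 <- stats::sd(values)
  extreme <- values[abs(values) > 0.9]
  if (length(extreme) >= 2) {
    mu1 <- mean(extreme)
    s1 <- max(stats::sd(extreme), 2 * s0, 0.3)
    pi1 <- min(0.5, max(0.01, length(extreme) / n))
  } else {
    k <- max(2L, ceiling(0.05 * n))
    extreme <- values[order(abs(values), decreasing = TRUE)][seq_len(k)]
    mu1 <- mean(extreme)
    s1 <- max(3 * s0, 0.3)
    pi1 <- 0.02
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  post <- rep(0, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    l1 <- log(pi1) + stats::dnorm(values, mu1, s1, log = TRUE)
    l0 <- log1p(-pi1) + stats::dnorm(values, mu0, s0, log = TRUE)
    mx <- pmax(l1, l0)
    den <- mx + log(exp(l1 - mx) + exp(l0 - mx))
    post <- exp(l1 - den)
    ll <- sum(den)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M step
    w1 <- sum(post)
    pi1 <- min(1 - 1e-9, max(1e-9, w1 / n))
    if (w1 > 1e-12) {
      mu1 <- sum(post * values) / w1
      s1 <- max(sqrt(sum(post * (values - mu1)^2) / w1), 1e-4)
    }
    w0 <- n - w1
    if (w0 > 1e-12) {
      mu0 <- sum((1 - post) * values) / w0
      s0 <- max(sqrt(sum((1 - post) * (values - mu0)^2) / w0), 1e-4)
    }
  }
  # orient: the variant component lies farther from 0 (tie: larger variance)
  swap <- abs(mu0) > abs(mu1) || (abs(mu0) == abs(mu1) && s0 > s1)
  if (swap) {
    tmp <- c(mu1, s1)
    mu1 <- mu0; s1 <- s0
    mu0 <- tmp[1]; s0 <- tmp[2]
    pi1 <- 1 - pi1
    post <- 1 - post
  }
  structure(list(pi = pi1, mu_variant = mu1, sigma_variant = s1,
                 mu_null = mu0, sigma_null = s0, posterior = post,
                 loglik = ll_trace, n_iter = iter, converged = converged),
            class = "cnv_mixture")
}

#' @export
print.cnv_mixture <- function(x, ...) {
  cat(sprintf("cnv_mixture: pi = %.4f, variant N(%.3f, %.3f^2), null N(%.3f, %.3f^2), %d iter%s\n",
              x$pi, x$mu_variant, x$sigma_variant, x$mu_null, x$sigma_null,
              x$n_iter, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Call per-fragment CNVs from a mixture fit
#'
#' @param fit A `cnv_mixture` fitted on `signals$signal` (same order).
#' @param signals Fragment signal table for the same genotype.
#' @param p_min Posterior threshold (strict `>`).
#' @param min_abs_log2 Absolute log2 ratio threshold (strict `>`).
#' @return `data.frame` (`fragment_id`, `genotype`, `class`
#'   (`UpCNV`/`DownCNV/PAV`), `log2`, `posterior`) with one row per called
#'   fragment.
#' @export
call_cnvs <- function(fit, signals, p_min = 0.95, min_abs_log2 = 0.9) {
  stopifnot(inherits(fit, "cnv_mixture"),
            length(fit$posterior) == nrow(signals))
  hit <- fit$posterior > p_min & abs(signals$signal) > min_abs_log2
  out <- data.frame(fragment_id = signals$fragment_id[hit],
                    genotype = signals$genotype[hit],
                    class = ifelse(signals$signal[hit] > 0, "UpCNV", "DownCNV/PAV"),
                    log2 = signals$signal[hit],
                    posterior = fit$posterior[hit],
                    stringsAsFactors = FALSE)
  stopifnot(all(out$posterior > p_min), all(abs(out$log2) > min_abs_log2))
  rownames(out) <- NULL
  out
}

#' Fit and call CNVs for every genotype of a panel
#'
#' @param signals Fragment signal table over all genotypes.
#' @inheritParams call_cnvs
#' @inheritParams fit_two_component_em
#' @return List with `calls` (row-bound call table) and `fits` (per-genotype
#'   `cnv_mixture`).
#' @export
call_cnv_panel <- function(signals, p_min = 0.95, min_abs_log2 = 0.9,
                           tol = 1e-8, max_iter = 500) {
  gts <- unique(signals$genotype)
  fits <- list()
  calls <- list()
  for (gt in gts) {
    sg <- signals[signals$genotype == gt, , drop = FALSE]
    fit <- fit_two_component_em(sg$signal, tol = tol, max_iter = max_iter)
    fits[[gt]] <- fit
    calls[[gt]] <- call_cnvs(fit, sg, p_min = p_min, min_abs_log2 = min_abs_log2)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  list(calls = out, fits = fits)
}

#' Merge consecutive same-class calls into CNV events
#'
#' Maximal runs of called fragments that are consecutive in a contig's
#' fragment order and share a class become one event; singleton runs are kept
#' (size 1).
#'
#' @param calls Call table from [call_cnvs()].
#' @param fragments Fragment table (defines the per-contig fragment order).
#' @return `data.frame` (`contig`, `genotype`, `class`, `n_fragments`,
#'   `fragment_ids`, `start`, `end`).
#' @export
merge_consecutive_events <- function(calls, fragments) {
  if (!all(calls$fragment_id %in% fragments$fragment_id))
    stop("calls reference unknown fragments")
  ord <- fragments[order(fragments$contig, fragments$start), , drop = FALSE]
  ord$rank <- stats::ave(seq_len(nrow(ord)), ord$contig, FUN = seq_along)
  m <- merge(calls, ord[, c("fragment_id", "contig", "start", "end", "rank")],
             by = "fragment_id")
  out <- list()
  for (key in unique(paste(m$genotype, m$contig, sep = "\r"))) {
    gt <- sub("\r.*", "", key)
    ctg <- sub(".*\r", "", key)
    g <- m[m$genotype == gt & m$contig == ctg, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    brk <- cumsum(c(1L, diff(g$rank) != 1L | g$class[-1] != g$class[-nrow(g)]))
    for (b in unique(brk)) {
      e <- g[brk == b, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, genotype = gt, class = e$class[1],
        n_fragments = nrow(e),
        fragment_ids = paste(e$fragment_id, collapse = ","),
        start = min(e$start), end = max(e$end), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), genotype = character(0),
               class = character(0), n_fragments = integer(0),
               fragment_ids = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Concordance between two call sets
#'
#' Fraction of calls in `calls_a` (fragment + class, and genotype when
#' present in both) that are also present in `calls_b`, plus the symmetric
#' Jaccard fraction. Used to compare calls from two array layouts or two
#' independent replicates of the same truth.
#'
#' @param calls_a,calls_b Call tables over the same fragment universe.
#' @return List with `forward` (|A intersect B| / |A|) and `symmetric`
#'   (|A intersect B| / |A union B|).
#' @export
cross_design_concordance <- function(calls_a, calls_b) {
  if (!nrow(calls_a)) stop("empty reference call set: concordance undefined")
  with_gt <- "genotype" %in% names(calls_a) && "genotype" %in% names(calls_b)
  key <- function(x) if (with_gt) paste(x$genotype, x$fragment_id, x$class)
                     else paste(x$fragment_id, x$class)
  a <- unique(key(calls_a))
  b <- unique(key(calls_b))
  list(forward = length(intersect(a, b)) / length(a),
       symmetric = length(intersect(a, b)) / length(union(a, b)))
}
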
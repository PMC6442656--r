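# Beta-binomial machinery behind the truncal-absence test.
#
# The model is parametrised by a mean mu and an intra-class overdispersion
# rho in [0, 1).  rho = 0 is the binomial limit; otherwise the shape
# parameters are alpha = mu (1 - rho) / rho and beta = (1 - mu)(1 - rho) / rho,
# so the concentration alpha + beta = (1 - rho) / rho depends on rho alone.

.RHO_EPS <- 1e-8

bb_shapes <- function(mu, rho) {
  list(alpha = mu * (1 - rho) / rho, beta = (1 - mu) * (1 - rho) / rho)
}

#' Beta-binomial probability mass
#'
#' Density of the beta-binomial distribution in mean/overdispersion
#' parametrisation. `rho = 0` gives the plain binomial.
#'
#' @param x Number of variant reads (vector).
#' @param size Total depth (vector, recycled).
#' @param mu Mean variant allele fraction in (0, 1).
#' @param rho Overdispersion in \[0, 1).
#' @param log Return log-density?
#' @return Numeric vector of (log-)probabilities.
#' @export
dbetabinom <- function(x, size, mu, rho, log = FALSE) {
  stopifnot(mu >= 0, mu <= 1, rho >= 0, rho < 1)
  if (rho <= .RHO_EPS)
    return(stats::dbinom(x, size, mu, log = log))
  s <- bb_shapes(mu, rho)
  lp <- lchoose(size, x) + lbeta(x + s$alpha, size - x + s$beta) -
    lbeta(s$alpha, s$beta)
  lp[x < 0 | x > size] <- -Inf
  if (log) lp else exp(lp)
}

#' Beta-binomial random deviates
#'
#' @param n Number of draws.
#' @param size Depths (recycled to length `n`).
#' @param mu,rho Mean and overdispersion (see [dbetabinom()]).
#' @return Integer vector of variant-read counts.
#' @export
rbetabinom <- function(n, size, mu, rho) {
  size <- rep_len(size, n)
  if (mu <= 0) return(integer(n))
  if (rho <= .RHO_EPS) return(stats::rbinom(n, size, mu))
  s <- bb_shapes(mu, rho)
  p <- stats::rbeta(n, s$alpha, s$beta)
  stats::rbinom(n, size, p)
}

#' Expected variant allele fraction at a given purity
#'
#' For a clonal mutation present in `multiplicity` copies per tumour cell at
#' a locus with tumour total copy number `total_cn` and normal copy number
#' `normal_cn`, the expected fraction of variant reads in a sample of purity
#' `purity` is
#' `f(pi) = pi * m / (pi * CNt + (1 - pi) * CNn)`.
#' This is the curve used to rescale a truncal VAF model trained on a
#' high-purity tumour-mass sample down to, e.g., a 1%-purity margin.
#'
#' @param purity Tumour purity in \[0, 1\] (vectorised).
#' @param multiplicity Mutated copies per tumour cell (>= 1).
#' @param total_cn Tumour total copy number at the locus.
#' @param normal_cn Normal (germline) copy number, 2 for autosomes.
#' @return Expected VAF, same length as the longest argument.
#' @export
expected_vaf <- function(purity, multiplicity = 1, total_cn = 2, normal_cn = 2) {
  n <- max(length(purity), length(multiplicity), length(total_cn),
           length(normal_cn))
  purity <- rep_len(purity, n)
  multiplicity <- rep_len(multiplicity, n)
  total_cn <- rep_len(total_cn, n)
  normal_cn <- rep_len(normal_cn, n)
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  denom <- purity * total_cn + (1 - purity) * normal_cn
  if (any(denom <= 0))
    stop("no DNA at locus: purity * total_cn + (1 - purity) * normal_cn = 0")
  ifelse(purity == 0, 0, purity * multiplicity / denom)
}

# Maximum-likelihood fit of (mu, rho) from paired (alt, depth) counts.
# Method-of-moments initialisation, Nelder-Mead on the logit scale (robust
# when the optimum sits at the rho -> 0 binomial boundary).
fit_bb_mle <- function(alt, depth) {
  stopifnot(length(alt) == length(depth), all(alt <= depth), all(depth > 0))
  if (all(alt == 0))
    stop("cannot fit a truncal VAF model: all variant read counts are zero")
  vaf <- alt / depth
  mu0 <- min(max(sum(alt) / sum(depth), 1e-4), 1 - 1e-4)
  nbar <- mean(depth)
  v <- stats::var(vaf)
  if (!is.finite(v)) v <- 0
  rho0 <- (v - mu0 * (1 - mu0) / nbar) / (mu0 * (1 - mu0) * (1 - 1 / nbar))
  rho0 <- min(max(rho0, 1e-4), 0.5)
  nll <- function(th) {
    -sum(dbetabinom(alt, depth, stats::plogis(th[1]), stats::plogis(th[2]),
                    log = TRUE))
  }
  opt <- stats::optim(c(stats::qlogis(mu0), stats::qlogis(rho0)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (opt$convergence != 0 || !is.finite(opt$value))
    stop("beta-binomial fit did not converge: code ", opt$convergence,
         if (!is.null(opt$message)) paste0(" (", opt$message, ")"))
  rho <- stats::plogis(opt$par[2])
  if (rho <= .RHO_EPS) rho <- 0
  list(mu = stats::plogis(opt$par[1]), rho = rho, loglik = -opt$value)
}

new_bb_fit <- function(mu, rho, total_cn, major_cn, sample_id = NA_character_,
                       purity = NA_real_, multiplicity = 1L,
                       n_training = NA_integer_, pooled = FALSE) {
  s <- if (rho > 0) bb_shapes(mu, rho) else list(alpha = NA_real_, beta = NA_real_)
  structure(
    list(mu = mu, rho = rho, alpha = s$alpha, beta = s$beta,
         total_cn = total_cn, major_cn = major_cn, sample_id = sample_id,
         purity = purity, multiplicity = multiplicity,
         n_training = n_training, pooled = pooled),
    class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf(
    "beta-binomial truncal VAF fit (CN %d/%d%s): mu = %.4f, rho = %.3g, n = %d\n",
    x$total_cn, x$major_cn, if (x$pooled) ", pooled" else "",
    x$mu, x$rho, x$n_training))
  invisible(x)
}

#' Fit beta-binomial truncal VAF models, one per copy-number state
#'
#' Fits a beta-binomial distribution to the variant read counts of putative
#' truncal SNVs observed in one high-purity training sample, separately for
#' each copy-number state `(total_cn, major_cn)`. States with fewer than
#' `min_training` SNVs are pooled into the nearest state that has enough
#' (nearest by total then major copy number) and flagged.
#'
#' @param counts Data frame with columns `alt_count`, `depth` and optionally
#'   `total_cn`, `major_cn` (default diploid heterozygous, 2/1).
#' @param sample_id,purity Identity and purity of the training sample; the
#'   purity is used to infer the mutation multiplicity implied by the fitted
#'   mean, which later drives purity rescaling.
#' @param normal_cn Germline copy number (default 2).
#' @param min_training Minimum SNVs per copy-number state (default 10).
#' @return A `bb_fits` object: list of [`bb_fit`][fit_betabinomial] models
#'   plus a state map recording which fit serves each copy-number state and
#'   whether it was pooled.
#' @export
fit_betabinomial <- function(counts, sample_id = NA_character_,
                             purity = NA_real_, normal_cn = 2,
                             min_training = 10) {
  stopifnot(is.data.frame(counts),
            all(c("alt_count", "depth") %in% names(counts)))
  if (is.null(counts$total_cn)) counts$total_cn <- 2L
  if (is.null(counts$major_cn)) counts$major_cn <- 1L
  if (nrow(counts) == 0) stop("no training SNVs supplied")
  key <- paste(counts$total_cn, counts$major_cn, sep = "/")
  states <- unique(data.frame(total_cn = counts$total_cn,
                              major_cn = counts$major_cn,
                              key = key, stringsAsFactors = FALSE))
  states <- states[order(states$total_cn, states$major_cn), , drop = FALSE]
  sizes <- table(key)[states$key]

  big <- states$key[sizes >= min_training]
  if (length(big) == 0) {
    # nothing reaches min_training: pool everything into one flagged fit
    target <- rep(states$key[which.max(sizes)], nrow(states))
  } else {
    target <- vapply(seq_len(nrow(states)), function(i) {
      if (states$key[i] %in% big) return(states$key[i])
      bigs <- states[states$key %in% big, , drop = FALSE]
      d <- abs(bigs$total_cn - states$total_cn[i]) * 10 +
        abs(bigs$major_cn - states$major_cn[i])
      bigs$key[which.min(d)]
    }, character(1))
  }

  fits <- list()
  for (tk in unique(target)) {
    members <- key %in% states$key[target == tk]
    sub <- counts[members, , drop = FALSE]
    st <- states[states$key == tk, , drop = FALSE]
    ml <- fit_bb_mle(sub$alt_count, sub$depth)
    m <- if (is.na(purity)) 1L else
      estimate_multiplicity(ml$mu, purity, st$total_cn, normal_cn, st$major_cn)
    fits[[tk]] <- new_bb_fit(ml$mu, ml$rho, st$total_cn, st$major_cn,
                             sample_id = sample_id, purity = purity,
                             multiplicity = m, n_training = nrow(sub),
                             pooled = any(target == tk & states$key != tk))
  }
  state_map <- data.frame(total_cn = states$total_cn,
                          major_cn = states$major_cn,
                          fit = target,
                          pooled = states$key != target,
                          n_state = as.integer(sizes),
                          stringsAsFactors = FALSE)
  structure(list(fits = fits, state_map = state_map,
                 sample_id = sample_id, purity = purity,
                 normal_cn = normal_cn, min_training = min_training),
            class = "bb_fits")
}

#' @export
print.bb_fits <- function(x, ...) {
  cat(sprintf("beta-binomial truncal VAF models for sample %s (purity %.2f):\n",
              x$sample_id, x$purity))
  for (f in x$fits) print(f)
  invisible(x)
}

#' Look up the fit serving a copy-number state
#'
#' @param fits A `bb_fits` object from [fit_betabinomial()].
#' @param total_cn,major_cn Copy-number state of the query locus.
#' @return A `bb_fit`; if the exact state was never seen in training, the
#'   nearest trained state's fit is returned.
#' @export
lookup_fit <- function(fits, total_cn, major_cn) {
  sm <- fits$state_map
  hit <- which(sm$total_cn == total_cn & sm$major_cn == major_cn)
  if (length(hit) == 1) return(fits$fits[[sm$fit[hit]]])
  d <- abs(sm$total_cn - total_cn) * 10 + abs(sm$major_cn - major_cn)
  fits$fits[[sm$fit[which.min(d)]]]
}

#' Rescale a truncal VAF fit to a different purity
#'
#' Models the dilution of tumour DNA as multiplicative thinning of the
#' variant allele fraction: the fitted mean is moved by the ratio of
#' expected VAFs,
#' `mu' = mu * f(target_purity) / f(training_purity)`,
#' so rescaling to the training purity is the identity. A scaled Beta
#' keeps its *relative* dispersion, which for small means amounts to
#' preserving the shape parameter `alpha` while `beta` grows to match the
#' new mean; the overdispersion `rho = 1 / (1 + alpha + beta)` therefore
#' shrinks roughly in proportion to the mean. (Preserving the
#' concentration `alpha + beta` instead would drive `alpha` towards zero
#' at 1% purity, pile mass on zero variant reads, and leave the test
#' powerless at exactly the worst-case purity it is meant for.)
#' A `rho = 0` (binomial) fit stays binomial.
#'
#' @param fit A `bb_fit` trained at a known purity.
#' @param target_purity Purity at which the model should predict VAF
#'   (e.g. 0.01, the worst-case margin purity).
#' @param total_cn,major_cn Copy-number state at the target locus; defaults
#'   to the fit's training state. The training multiplicity is capped at the
#'   target major copy number.
#' @param normal_cn Germline copy number.
#' @return A new `bb_fit` with the rescaled mean and overdispersion.
#' @export
rescale_fit <- function(fit, target_purity, total_cn = fit$total_cn,
                        major_cn = fit$major_cn, normal_cn = 2) {
  stopifnot(inherits(fit, "bb_fit"))
  if (is.na(fit$purity))
    stop("fit has no training purity; cannot rescale")
  m <- min(fit$multiplicity, max(1L, major_cn))
  f_new <- expected_vaf(target_purity, m, total_cn, normal_cn)
  f_train <- expected_vaf(fit$purity, fit$multiplicity, fit$total_cn,
                          normal_cn)
  mu2 <- fit$mu * f_new / f_train
  if (mu2 <= 0)
    stop("degenerate rescaled model (expected VAF = 0); use target_purity > 0")
  mu2 <- min(mu2, 1 - 1e-12)
  rho2 <- if (fit$rho <= .RHO_EPS) 0 else {
    beta2 <- fit$alpha * (1 - mu2) / mu2
    1 / (1 + fit$alpha + beta2)
  }
  new_bb_fit(mu2, rho2, total_cn, major_cn, sample_id = fit$sample_id,
             purity = target_purity, multiplicity = m,
             n_training = fit$n_training, pooled = fit$pooled)
}

#' One-sided p-value for absence of a mutation
#'
#' Lower-tail probability `P(X <= x)` of observing at most `alt_observed`
#' variant reads in `depth` reads under the (purity-rescaled) beta-binomial
#' null that the mutation is truly truncal and therefore present. For
#' `x = 0` the closed form `P(X = 0) = B(alpha, beta + n) / B(alpha, beta)`
#' is evaluated in log space; `rho = 0` uses the binomial `(1 - mu)^n`
#' tail. Zero depth returns 1: no data can never reject presence.
#'
#' @param fit A `bb_fit`, typically from [rescale_fit()].
#' @param depth Read depth(s) at the tested locus.
#' @param alt_observed Observed variant read count(s).
#' @return p-value vector.
#' @export
absence_pvalue <- function(fit, depth, alt_observed) {
  stopifnot(inherits(fit, "bb_fit"))
  n <- max(length(depth), length(alt_observed))
  depth <- rep_len(as.integer(round(depth)), n)
  x <- rep_len(as.integer(round(alt_observed)), n)
  if (any(depth < 0) || any(x < 0) || any(x > depth))
    stop("need 0 <= alt_observed <= depth")
  p <- numeric(n)
  zero <- depth == 0
  p[zero] <- 1
  if (fit$rho <= .RHO_EPS) {
    p[!zero] <- stats::pbinom(x[!zero], depth[!zero], fit$mu)
  } else {
    a <- fit$alpha; b <- fit$beta
    for (i in which(!zero)) {
      if (x[i] == 0) {
        p[i] <- exp(lbeta(a, b + depth[i]) - lbeta(a, b))
      } else {
        k <- 0:x[i]
        p[i] <- sum(exp(lchoose(depth[i], k) +
                          lbeta(k + a, depth[i] - k + b) - lbeta(a, b)))
      }
    }
  }
  pmin(p, 1)
}
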
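#' Bivariate upper-orthant probability for two thresholded latent normals
#'
#' Under the latent-Gaussian dependence model, condition A is present when a
#' standard normal latent variable exceeds the (1 - pA) quantile, and
#' likewise for B with latent correlation `rho`. The joint prevalence
#' P(A, B) is then the upper-orthant probability of a bivariate standard
#' normal. Computed with deterministic bivariate-normal quadrature
#' (`mvtnorm`, TVPACK algorithm); the comonotone and countermonotone limits
#' return the Frechet bounds exactly.
#'
#' @param p_a,p_b marginal prevalences in (0, 1).
#' @param rho latent correlation in [-1, 1].
#' @return P(A, B), the expected joint prevalence.
#' @export
latent_joint_prob <- function(p_a, p_b, rho) {
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1, abs(rho) <= 1)
  if (rho >= 1 - 1e-12) return(min(p_a, p_b))
  if (rho <= -1 + 1e-12) return(max(p_a + p_b - 1, 0))
  if (abs(rho) < 1e-14) return(p_a * p_b)
  a <- stats::qnorm(1 - p_a)
  b <- stats::qnorm(1 - p_b)
  R <- matrix(c(1, rho, rho, 1), 2, 2)
  as.numeric(mvtnorm::pmvnorm(lower = c(a, b), upper = c(Inf, Inf),
                              corr = R, algorithm = mvtnorm::TVPACK()))
}

#' Calibrate the latent correlation producing a target joint prevalence
#'
#' Inverts [latent_joint_prob()] in `rho` by monotone bisection: the
#' orthant probability is strictly increasing in the latent correlation at
#' fixed margins, so the root is unique. This is how tests plant a disease
#' pair with a chosen lift: pick the target joint as lift x pA x pB and
#' calibrate.
#'
#' @param p_a,p_b marginal prevalences in (0, 1).
#' @param target_joint desired P(A, B); must lie strictly inside the
#'   Frechet interval (max(pA + pB - 1, 0), min(pA, pB)).
#' @param tol absolute tolerance on the achieved joint probability.
#' @return the latent correlation `rho` with
#'   `latent_joint_prob(p_a, p_b, rho) == target_joint` within `tol`.
#' @export
calibrate_dependence <- function(p_a, p_b, target_joint, tol = 1e-8) {
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1)
  lower <- max(p_a + p_b - 1, 0)
  upper <- min(p_a, p_b)
  if (target_joint <= lower) {
    stop("target_joint ", target_joint, " violates the Frechet lower bound ",
         "max(pA + pB - 1, 0) = ", lower)
  }
  if (target_joint >= upper) {
    stop("target_joint ", target_joint, " violates the Frechet upper bound ",
         "min(pA, pB) = ", upper)
  }
  lo <- -1 + 1e-9
  hi <- 1 - 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- latent_joint_prob(p_a, p_b, mid) - target_joint
    if (abs(f) < tol && (hi - lo) < 1e-10) break
    if (f < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# square-root factor of a correlation matrix; eigenvalues within the
# -1e-8 tolerance are clipped to zero so comonotone (singular) blocks work
corr_factor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  if (min(ev) < -1e-8) {
    stop("latent correlation is not positive semidefinite: smallest ",
         "eigenvalue ", format(min(ev)))
  }
  ev[ev < 0] <- 0
  e$vectors %*% diag(sqrt(ev), nrow = length(ev))
}

#' Simulate a survey cohort from a cohort specification
#'
#' Per stratum, draws `n` latent multivariate-normal vectors with the
#' stratum's latent correlation, and sets indicator k to 1 when the k-th
#' latent value exceeds the (1 - margin_k) standard-normal quantile, so the
#' expected prevalence of each condition equals its margin exactly. Survey
#' weights are drawn from the weight model (log-normal by default) and
#' rescaled so each stratum's mean weight is exactly 1. The draw is fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a [cohort_table()] with subject ids `<stratum>_<i>`.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  set.seed(spec$seed)
  cn <- spec$condition_names
  K <- length(cn)
  parts <- lapply(names(spec$strata), function(label) {
    s <- spec$strata[[label]]
    A <- corr_factor(s$latent_correlation)
    Z <- matrix(stats::rnorm(s$n * K), s$n, K) %*% t(A)
    thr <- stats::qnorm(1 - s$margins)
    ind <- t(t(Z) > thr)
    storage.mode(ind) <- "integer"
    colnames(ind) <- cn
    w <- draw_weights(spec$weight_model, s$n)
    cbind(
      data.frame(subject_id = paste0(label, "_", seq_len(s$n)),
                 stratum = label, weight = w,
                 stringsAsFactors = FALSE),
      as.data.frame(ind)
    )
  })
  validate_cohort_table(new_cohort_table(do.call(rbind, parts), cn))
}

draw_weights <- function(weight_model, n) {
  if (weight_model$family == "constant") return(rep(1, n))
  sdlog <- weight_model$dispersion
  if (sdlog == 0) return(rep(1, n))
  w <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  w / mean(w)
}

#' Exact expected pairwise structure implied by a cohort specification
#'
#' For every ordered condition pair within every stratum, returns the exact
#' expected margins, joint prevalence (by bivariate-normal orthant
#' integration of the latent model) and lift, plus a flag for pairs with
#' planted dependence (nonzero latent correlation). Serves as the oracle
#' against which estimates from a simulated cohort are checked.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `stratum`, `condition_a`, `condition_b`,
#'   `p_a`, `p_b`, `joint`, `lift`, `planted`.
#' @export
truth_table <- function(spec) {
  spec <- validate_cohort_spec(spec)
  cn <- spec$condition_names
  K <- length(cn)
  pairs <- expand.grid(a = seq_len(K), b = seq_len(K))
  pairs <- pairs[pairs$a != pairs$b, ]
  out <- lapply(names(spec$strata), function(label) {
    s <- spec$strata[[label]]
    joint <- mapply(function(i, j) {
      latent_joint_prob(s$margins[i], s$margins[j],
                        s$latent_correlation[i, j])
    }, pairs$a, pairs$b)
    data.frame(
      stratum = label,
      condition_a = cn[pairs$a], condition_b = cn[pairs$b],
      p_a = unname(s$margins[pairs$a]), p_b = unname(s$margins[pairs$b]),
      joint = joint,
      lift = unname(joint / (s$margins[pairs$a] * s$margins[pairs$b])),
      planted = abs(s$latent_correlation[cbind(pairs$a, pairs$b)]) > 0,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}
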
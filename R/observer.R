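# Forced-fusion and Bayesian-causal-inference observer models.
#
# The observer receives internal samples x_A ~ N(S_A, sigma_A^2) and
# x_V ~ N(S_V, sigma_V^2) and holds a central spatial prior N(mu_P,
# sigma_P^2).  Under a common cause the signals are fused with the prior,
# reliability weighted; under independent causes each modality is combined
# with the prior alone.  The BCI observer infers the causal structure by
# Bayes' rule and reads out a model-averaged estimate of the reported
# modality; the forced-fusion observer is the P_common = 1 special case.

# The 2 x 3 factorial model space: prestimulus attention (sigma fixed/free
# across attention) crossed with poststimulus report (forced fusion with
# sigma fixed/free across report, or BCI with a flexible late readout).
VARIANTS <- tibble::tribble(
  ~variant,                  ~inference, ~scheme,    ~k,
  "FF-att_fixed-rep_fixed",  "FF",       "none",     3L,
  "FF-att_free-rep_fixed",   "FF",       "att",      5L,
  "FF-att_fixed-rep_free",   "FF",       "rep",      5L,
  "FF-att_free-rep_free",    "FF",       "att_rep",  9L,
  "BCI-att_fixed",           "BCI",      "none",     4L,
  "BCI-att_free",            "BCI",      "att",      6L
)

#' The 2 x 3 factorial observer-model space
#'
#' @return A tibble with one row per model variant: the inference type
#'   (forced fusion or Bayesian causal inference), the conditioning scheme
#'   of the sensory noise parameters, and the free-parameter count.
#' @export
model_variants <- function() VARIANTS

scheme_levels <- function(scheme) {
  switch(scheme,
    none = "all",
    att = c("attA", "attV"),
    rep = c("repA", "repV"),
    att_rep = c("attA.repA", "attA.repV", "attV.repA", "attV.repV"),
    abort(paste0("unknown scheme: ", scheme))
  )
}

scheme_key <- function(scheme, attention, report) {
  switch(scheme,
    none = rep("all", length(attention)),
    att = paste0("att", attention),
    rep = paste0("rep", report),
    att_rep = paste0("att", attention, ".rep", report)
  )
}

#' Construct observer-model parameters
#'
#' @param variant One of the six codes in [model_variants()].
#' @param sigma_a,sigma_v Sensory noise s.d. in degrees: a scalar, or a
#'   vector named by the variant's conditioning levels (e.g. `c(attA = 4,
#'   attV = 6)` for `*-att_free` variants).  Scalars are expanded to all
#'   levels.
#' @param sigma_p Spatial prior s.d. in degrees.
#' @param p_common Common-cause prior probability (BCI variants only;
#'   forced fusion fixes it at 1).
#' @param mu_p Spatial prior mean in degrees (0, central bias).
#' @return An object of class `avbci_observer_params`.
#' @export
#' @examples
#' observer_params("BCI-att_free",
#'   sigma_a = c(attA = 4.5, attV = 6), sigma_v = c(attA = 1.5, attV = 1.1),
#'   sigma_p = 12, p_common = 0.6
#' )
observer_params <- function(variant, sigma_a, sigma_v, sigma_p,
                            p_common = NULL, mu_p = 0) {
  row <- VARIANTS[VARIANTS$variant == variant, ]
  if (nrow(row) == 0) {
    abort(paste0("unknown model variant: ", variant))
  }
  lv <- scheme_levels(row$scheme)
  expand <- function(s, what) {
    if (length(s) == 1 && is.null(names(s))) s <- setNames(rep(s, length(lv)), lv)
    if (!setequal(names(s), lv)) {
      abort(paste0("`", what, "` must be named by: ", paste(lv, collapse = ", ")))
    }
    s <- s[lv]
    if (any(!is.finite(s)) || any(s <= 0)) {
      abort(paste0("`", what, "` must be positive and finite."))
    }
    s
  }
  sigma_a <- expand(sigma_a, "sigma_a")
  sigma_v <- expand(sigma_v, "sigma_v")
  if (!is.finite(sigma_p) || sigma_p <= 0) abort("`sigma_p` must be positive.")
  if (row$inference == "FF") {
    p_common <- 1
  } else {
    if (is.null(p_common)) abort("BCI variants need `p_common`.")
    if (p_common < 0 || p_common > 1) abort("`p_common` must lie in [0, 1].")
  }
  structure(
    list(
      variant = variant, inference = row$inference, scheme = row$scheme,
      k = row$k, sigma_a = sigma_a, sigma_v = sigma_v,
      sigma_p = as.numeric(sigma_p), p_common = as.numeric(p_common),
      mu_p = as.numeric(mu_p)
    ),
    class = "avbci_observer_params"
  )
}

#' @export
print.avbci_observer_params <- function(x, ...) {
  cat("<avbci observer params> ", x$variant, " (k = ", x$k, ")\n", sep = "")
  cat("  sigma_A:", paste(names(x$sigma_a), round(x$sigma_a, 3), sep = "=",
                          collapse = ", "), "\n")
  cat("  sigma_V:", paste(names(x$sigma_v), round(x$sigma_v, 3), sep = "=",
                          collapse = ", "), "\n")
  cat("  sigma_P:", round(x$sigma_p, 3), " mu_P:", x$mu_p)
  if (x$inference == "BCI") cat("  P_common:", round(x$p_common, 3))
  cat("\n")
  invisible(x)
}

# Per-trial sigmas given the conditioning scheme.
sigma_at <- function(params, attention, report) {
  key <- scheme_key(params$scheme, attention, report)
  list(sa = unname(params$sigma_a[key]), sv = unname(params$sigma_v[key]))
}

#' Posterior probability of a common cause
#'
#' Bayes' rule over the two causal structures, with the Gaussian marginal
#' likelihoods of the internal samples obtained in closed form by
#' integrating the source locations against the spatial prior.
#'
#' @param x_a,x_v Internal samples (degrees); vectorised.
#' @param params An [observer_params()] object.
#' @param attention,report Condition levels selecting the sigmas for
#'   variants whose noise is condition specific.
#' @return `p(C = 1 | x_A, x_V)`, same length as the samples.
#' @export
posterior_common <- function(x_a, x_v, params, attention = "A", report = "A") {
  s <- sigma_at(params, attention, report)
  pc <- params$p_common
  if (pc >= 1) return(rep(1, length(x_a)))
  if (pc <= 0) return(rep(0, length(x_a)))
  va <- s$sa^2
  vv <- s$sv^2
  vp <- params$sigma_p^2
  mup <- params$mu_p
  d1 <- va * vv + va * vp + vv * vp
  ll1 <- -log(2 * pi) - 0.5 * log(d1) -
    0.5 * ((x_a - x_v)^2 * vp + (x_a - mup)^2 * vv + (x_v - mup)^2 * va) / d1
  ll2 <- -log(2 * pi) - 0.5 * log((va + vp) * (vv + vp)) -
    0.5 * ((x_a - mup)^2 / (va + vp) + (x_v - mup)^2 / (vv + vp))
  1 / (1 + exp(ll2 + log1p(-pc) - ll1 - log(pc)))
}

#' Fusion and segregation estimates for internal samples
#'
#' Reliability-weighted combination of the samples with the spatial prior:
#' the fused (common cause) estimate uses both modalities, the segregation
#' (independent causes) estimates use one modality each.
#'
#' @inheritParams posterior_common
#' @return A tibble with columns `s_fused`, `s_seg_a`, `s_seg_v`.
#' @export
component_estimates <- function(x_a, x_v, params, attention = "A",
                                report = "A") {
  s <- sigma_at(params, attention, report)
  va <- s$sa^2
  vv <- s$sv^2
  vp <- params$sigma_p^2
  mup <- params$mu_p
  tibble(
    s_fused = (x_a / va + x_v / vv + mup / vp) / (1 / va + 1 / vv + 1 / vp),
    s_seg_a = (x_a / va + mup / vp) / (1 / va + 1 / vp),
    s_seg_v = (x_v / vv + mup / vp) / (1 / vv + 1 / vp)
  )
}

#' Model-averaged final location estimates
#'
#' The final estimate of each modality is the fused estimate and that
#' modality's segregation estimate weighted by the posterior probabilities
#' of the causal structures (model averaging).  Forced-fusion variants
#' return the fused estimate for both modalities.
#'
#' @inheritParams posterior_common
#' @return A tibble with columns `p_c1`, `s_fused`, `s_seg_a`, `s_seg_v`,
#'   `s_final_a`, `s_final_v`.
#' @export
final_estimates <- function(x_a, x_v, params, attention = "A", report = "A") {
  est <- component_estimates(x_a, x_v, params, attention, report)
  p1 <- if (params$inference == "FF") {
    rep(1, length(x_a))
  } else {
    posterior_common(x_a, x_v, params, attention, report)
  }
  est |>
    mutate(
      p_c1 = p1,
      s_final_a = p1 * .data$s_fused + (1 - p1) * .data$s_seg_a,
      s_final_v = p1 * .data$s_fused + (1 - p1) * .data$s_seg_v,
      .before = 1
    )
}

#' Predicted 3-button response distribution for one condition
#'
#' Marginalises the deterministic sample-to-button mapping over the
#' bivariate Gaussian of the internal samples, either by Monte-Carlo
#' simulation (the fitting route, matching the C++ likelihood kernel) or
#' by stratified numerical integration (`method = "quadrature"`, a slower
#' independent route usable as an oracle).
#'
#' @param params An [observer_params()] object.
#' @param condition A list or one-row data frame with `aloc`, `vloc`,
#'   `attention`, `report`.
#' @param method `"simulation"` or `"quadrature"`.
#' @param n_sim Number of simulated internal-sample pairs.
#' @param seed Seed for the simulation draws.
#' @param grid_n Strata per dimension for the quadrature method.
#' @param locations Button locations (degrees).
#' @return A tibble with columns `button` and `prob` (sums to 1).
#' @export
predict_response_probs <- function(params, condition,
                                   method = c("simulation", "quadrature"),
                                   n_sim = 10000, seed = 1, grid_n = 301,
                                   locations = c(-9, 0, 9)) {
  method <- match.arg(method)
  condition <- as.list(condition)
  need <- c("aloc", "vloc", "attention", "report")
  if (!all(need %in% names(condition))) {
    abort("`condition` needs fields aloc, vloc, attention, report.")
  }
  locations <- sort(locations)
  s <- sigma_at(params, condition$attention, condition$report)

  if (method == "simulation") {
    if (n_sim < 1) abort("`n_sim` must be at least 1.")
    z <- with_seed(seed, matrix(rnorm(2 * n_sim), ncol = 2))
    p <- cell_response_probs_cpp(
      za = z[, 1, drop = FALSE], zv = z[, 2, drop = FALSE],
      aloc = condition$aloc, vloc = condition$vloc,
      sa = s$sa, sv = s$sv,
      report_a = condition$report == "A",
      sp = params$sigma_p, mup = params$mu_p,
      pc = params$p_common, forced_fusion = params$inference == "FF",
      buttons = locations
    )[, 1]
  } else {
    # stratification of each Gaussian in probability space: grid_n
    # equiprobable inner strata, with the outermost stratum on each side
    # subdivided so the far tails are represented rather than truncated
    tail_sub <- 64
    bounds <- unique(c(
      seq(0, 1 / grid_n, length.out = tail_sub + 1),
      seq_len(grid_n - 1) / grid_n,
      seq(1 - 1 / grid_n, 1, length.out = tail_sub + 1)
    ))
    u <- (bounds[-1] + bounds[-length(bounds)]) / 2
    wt <- diff(bounds)
    xa <- condition$aloc + s$sa * qnorm(u)
    xv <- condition$vloc + s$sv * qnorm(u)
    g <- tidyr::expand_grid(x_a = xa, x_v = xv)
    gw <- as.vector(outer(wt, wt))
    est <- final_estimates(g$x_a, g$x_v, params,
                           condition$attention, condition$report)
    e <- if (condition$report == "A") est$s_final_a else est$s_final_v
    btn <- nearest_button(e, locations)
    p <- as.numeric(tapply(gw, factor(btn, levels = locations), sum,
                           default = 0))
    p <- p / sum(p)
  }
  tibble(button = locations, prob = p)
}
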
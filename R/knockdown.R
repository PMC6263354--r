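#' Two-stage gene expression parameters
#'
#' Linear (non-saturating) mRNA/protein kinetics:
#' `dm/dt = k_m - d_m * m`, `dp/dt = k_p * m - d_p * p`.
#' The default protein decay represents dilution at a 1/h growth rate.
#'
#' @param k_m mRNA synthesis rate (a.u./h).
#' @param k_p translation rate (a.u./h per mRNA).
#' @param d_m mRNA decay rate (1/h).
#' @param d_p protein decay + dilution rate (1/h).
#' @return An object of class `expression_params`.
#' @export
expression_params <- function(k_m = 10, k_p = 10, d_m = 6, d_p = 1) {
  if (any(c(k_m, k_p, d_m, d_p) <= 0)) stop("all rates must be > 0")
  structure(list(k_m = k_m, k_p = k_p, d_m = d_m, d_p = d_p),
            class = "expression_params")
}

#' Knockdown mechanism configuration
#'
#' Three repression mechanisms act on the two-stage expression model once
#' induced: CRISPRi blocks a fraction of transcription initiation
#' (multiplies `k_m` by `1 - crispri_block`), an sRNA destabilizes the
#' mRNA (adds `srna_extra_decay` to `d_m`), and a targeted protease
#' degrades the already-made protein pool (adds `protease_extra_decay` to
#' `d_p`). Any combination can be active.
#'
#' @param crispri_block fraction of transcription blocked, in `[0, 1)`.
#' @param srna_extra_decay additional mRNA decay (1/h), >= 0.
#' @param protease_extra_decay additional protein decay (1/h), >= 0.
#' @param induction_time time the mechanisms switch on (h).
#' @return An object of class `knockdown_config`.
#' @export
knockdown_config <- function(crispri_block = 0, srna_extra_decay = 0,
                             protease_extra_decay = 0, induction_time = 2) {
  if (crispri_block < 0 || crispri_block >= 1)
    stop("crispri_block must be in [0, 1)")
  if (srna_extra_decay < 0 || protease_extra_decay < 0)
    stop("extra decay rates must be >= 0")
  structure(list(crispri_block = crispri_block,
                 srna_extra_decay = srna_extra_decay,
                 protease_extra_decay = protease_extra_decay,
                 induction_time = induction_time),
            class = "knockdown_config")
}

#' Steady-state fold repression
#'
#' In the linear model the mechanism factors decouple:
#' `fold = 1/(1 - block) * (d_m + srna)/d_m * (d_p + protease)/d_p`.
#' This closed form is the t -> infinity limit of [simulate_knockdown()].
#'
#' @param p an [expression_params()].
#' @param k a [knockdown_config()].
#' @return Fold repression (uninduced / induced steady protein),
#'   dimensionless; `Inf` when transcription is fully blocked.
#' @export
steady_state_fold <- function(p, k) {
  stopifnot(inherits(p, "expression_params"),
            inherits(k, "knockdown_config"))
  (1 / (1 - k$crispri_block)) *
    ((p$d_m + k$srna_extra_decay) / p$d_m) *
    ((p$d_p + k$protease_extra_decay) / p$d_p)
}

#' Calibrate one mechanism to a target fold
#'
#' Inverts [steady_state_fold()] for a single mechanism: returns the
#' `crispri_block`, `srna_extra_decay` or `protease_extra_decay` value that
#' alone produces the requested fold repression.
#'
#' @param fold target fold repression, >= 1.
#' @param mechanism one of `"crispri"`, `"srna"`, `"protease"`.
#' @param p an [expression_params()] (needed for the decay-rate
#'   mechanisms).
#' @param induction_time passed through to the returned config.
#' @return A [knockdown_config()] realizing the target fold.
#' @export
calibrate_knockdown <- function(fold,
                                mechanism = c("crispri", "srna",
                                              "protease"),
                                p = expression_params(),
                                induction_time = 2) {
  mechanism <- match.arg(mechanism)
  if (fold < 1) stop("fold must be >= 1")
  switch(mechanism,
    crispri = knockdown_config(crispri_block = 1 - 1 / fold,
                               induction_time = induction_time),
    srna = knockdown_config(srna_extra_decay = (fold - 1) * p$d_m,
                            induction_time = induction_time),
    protease = knockdown_config(protease_extra_decay = (fold - 1) * p$d_p,
                                induction_time = induction_time))
}

#' Simulate a knockdown time course
#'
#' Integrates the linear two-stage ODE with [deSolve::ode()]. The system
#' starts at its pre-induction steady state; at `induction_time` the
#' configured mechanisms switch on and the protein relaxes toward the
#' repressed steady state. The returned trajectory is normalized to the
#' pre-induction steady-state protein level.
#'
#' @param p an [expression_params()].
#' @param k a [knockdown_config()] with `induction_time < horizon`.
#' @param horizon simulated span (h).
#' @param dt output sampling step (h); must resolve the fastest
#'   post-induction timescale (`dt < 1 / max(rate)`).
#' @return A [time_course()] of normalized protein level.
#' @export
simulate_knockdown <- function(p, k, horizon = 18, dt = 0.025) {
  stopifnot(inherits(p, "expression_params"),
            inherits(k, "knockdown_config"))
  if (k$induction_time >= horizon)
    stop("induction_time must be < horizon")
  fastest <- max(p$d_m + k$srna_extra_decay, p$d_p + k$protease_extra_decay)
  if (dt >= 1 / fastest)
    stop(sprintf("dt = %g h does not resolve the fastest timescale %g h",
                 dt, 1 / fastest))
  m0 <- p$k_m / p$d_m
  p0 <- p$k_p * m0 / p$d_p
  rhs <- function(t, y, parms) {
    list(c(parms["km"] - parms["dm"] * y[1],
           p$k_p * y[1] - parms["dp"] * y[2]))
  }
  # integrate the pre- and post-induction regimes separately so the
  # parameter switch is not smoothed over by the adaptive solver
  t_post <- seq(k$induction_time, horizon, by = dt)
  if (t_post[length(t_post)] < horizon) t_post <- c(t_post, horizon)
  post_parms <- c(km = p$k_m * (1 - k$crispri_block),
                  dm = p$d_m + k$srna_extra_decay,
                  dp = p$d_p + k$protease_extra_decay)
  sol_post <- deSolve::ode(y = c(m = m0, prot = p0), times = t_post,
                           func = rhs, parms = post_parms,
                           method = "lsoda")
  if (k$induction_time > 0) {
    # pre-induction the system sits at its steady state
    t_pre <- seq(0, k$induction_time, by = dt)
    if (t_pre[length(t_pre)] < k$induction_time)
      t_pre <- c(t_pre, k$induction_time)
    times <- c(t_pre, t_post[-1L])
    prot <- c(rep(p0, length(t_pre)), sol_post[-1L, "prot"])
  } else {
    times <- t_post
    prot <- sol_post[, "prot"]
  }
  time_course(times, prot / p0, name = "protein")
}

#' Estimate fold repression from population fluorescence samples
#'
#' Fold change is the ratio of the population medians (uninduced over
#' induced), with a seeded bootstrap confidence interval (percentile
#' method, 1,000 resamples).
#'
#' @param pre uninduced population samples (a.u.), >= 50 values.
#' @param post induced population samples (a.u.), >= 50 values.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return List with `fold`, `ci` (two-sided interval), and `infinite`
#'   (TRUE when the induced median is zero).
#' @export
estimate_fold <- function(pre, post, n_boot = 1000, conf = 0.95,
                          seed = 1L) {
  if (length(pre) < 50 || length(post) < 50)
    stop("need >= 50 samples per population")
  med_pre <- stats::median(pre)
  med_post <- stats::median(post)
  if (med_post == 0) {
    return(list(fold = Inf, ci = c(NA_real_, NA_real_), infinite = TRUE))
  }
  fold <- med_pre / med_post
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      a <- stats::median(sample(pre, replace = TRUE))
      b <- stats::median(sample(post, replace = TRUE))
      if (b == 0) NA_real_ else a / b
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(fold = fold, ci = ci, infinite = FALSE)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Read a knockdown scenario from YAML
#'
#' Scenario files carry `params` (fields of [expression_params()]),
#' `mechanisms` (fields of [knockdown_config()]) and optional `horizon` /
#' `dt`.
#'
#' @param path YAML file path.
#' @return List with `params`, `config`, `horizon`, `dt`.
#' @export
read_knockdown_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  p <- do.call(expression_params, as.list(x$params))
  k <- do.call(knockdown_config, as.list(x$mechanisms))
  list(params = p, config = k,
       horizon = if (is.null(x$horizon)) 18 else x$horizon,
       dt = if (is.null(x$dt)) 0.025 else x$dt)
}
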
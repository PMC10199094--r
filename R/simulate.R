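#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a longitudinal mouse study: `n_mice` animals
#' measured at the ages in `schedule`, with a linear coupling between the
#' monthly change in discrimination index (DI) and the monthly change in
#' inner nuclear layer (INL) thickness. For each mouse and each adjacent
#' visit interval a DI monthly change `g ~ Normal(di_change_mean,
#' di_change_sd)` is drawn; the DI trajectory is integrated from a baseline
#' and clamped to `[-1, 1]` (DI is bounded by definition); the INL monthly
#' change is then `coupling_slope * g + coupling_intercept + eps` with
#' `eps ~ Normal(0, residual_sd)`, where `g` is the realized (post-clamp)
#' DI change, so the emitted data follow the coupling model exactly. The
#' other layers (NFL-GCL-IPL composite, ONL) drift linearly with their own
#' noise, uncoupled to cognition; total retinal thickness is the sum of the
#' three layers plus a fixed extra-layer margin. Each visit is emitted as
#' two eyes with independent Normal thickness perturbations; exploration
#' times are synthesized to realize each DI exactly.
#'
#' The default `residual_sd` is chosen so that the model-implied coefficient
#' of determination of the INL-change on DI-change regression,
#' `r2 = a^2 s^2 / (a^2 s^2 + residual_sd^2)` (see [implied_r2()]), equals
#' 0.297.
#'
#' @param n_mice Number of animals (default 12).
#' @param schedule Strictly increasing visit ages in months (default 4, 6, 9).
#' @param coupling_slope,coupling_intercept Linear map from DI change per
#'   month to INL change in pixels per month (defaults 3.046, -0.5284).
#' @param di_change_mean,di_change_sd Mean and SD of the per-interval DI
#'   monthly change (defaults -0.0579, 0.1643 per month).
#' @param residual_sd SD of the INL-change noise around the coupling line,
#'   pixels per month.
#' @param di_baseline_mean,di_baseline_sd Baseline DI distribution at the
#'   first visit.
#' @param inl_baseline_mean,inl_baseline_sd Baseline INL thickness, pixels.
#' @param nfl_baseline_mean,nfl_baseline_sd,nfl_drift NFL-GCL-IPL composite
#'   baseline (pixels) and drift (pixels per month).
#' @param onl_baseline_mean,onl_baseline_sd,onl_drift ONL baseline and drift.
#' @param layer_noise_sd Per-interval noise SD on the nuisance layer monthly
#'   changes, pixels per month.
#' @param tr_margin Extra thickness of the layers not individually measured,
#'   added to NFL-GCL-IPL + INL + ONL to give total retinal thickness.
#' @param inter_eye_sd SD of the independent per-eye thickness perturbation,
#'   pixels.
#' @param total_exploration_range Uniform range for the total exploration
#'   time, seconds.
#' @param clamp_warn_frac Warn when more than this fraction of DI
#'   integrations hit the `[-1, 1]` bound.
#' @param seed Integer seed; same seed, same cohort, byte for byte.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_mice = 12,
                          schedule = c(4, 6, 9),
                          coupling_slope = 3.046,
                          coupling_intercept = -0.5284,
                          di_change_mean = -0.0579,
                          di_change_sd = 0.1643,
                          residual_sd = coupling_slope * di_change_sd *
                            sqrt((1 - 0.297) / 0.297),
                          di_baseline_mean = 0.35,
                          di_baseline_sd = 0.10,
                          inl_baseline_mean = 40,
                          inl_baseline_sd = 2,
                          nfl_baseline_mean = 70,
                          nfl_baseline_sd = 3,
                          nfl_drift = -0.2,
                          onl_baseline_mean = 60,
                          onl_baseline_sd = 3,
                          onl_drift = -0.1,
                          layer_noise_sd = 0.3,
                          tr_margin = 8,
                          inter_eye_sd = 0.75,
                          total_exploration_range = c(20, 60),
                          clamp_warn_frac = 0.1,
                          seed = 1L) {
  if (n_mice < 0 || n_mice != round(n_mice)) {
    abort("n_mice must be a nonnegative integer", class = "retinocog_domain_error")
  }
  if (length(schedule) < 2 || any(diff(schedule) <= 0)) {
    abort("schedule must be strictly increasing with at least 2 visits",
          class = "retinocog_domain_error")
  }
  if (di_change_sd < 0 || residual_sd < 0 || inter_eye_sd < 0 || layer_noise_sd < 0) {
    abort("standard deviations must be >= 0", class = "retinocog_domain_error")
  }
  structure(
    list(
      n_mice = as.integer(n_mice), schedule = as.numeric(schedule),
      coupling_slope = coupling_slope, coupling_intercept = coupling_intercept,
      di_change_mean = di_change_mean, di_change_sd = di_change_sd,
      residual_sd = residual_sd,
      di_baseline_mean = di_baseline_mean, di_baseline_sd = di_baseline_sd,
      inl_baseline_mean = inl_baseline_mean, inl_baseline_sd = inl_baseline_sd,
      nfl_baseline_mean = nfl_baseline_mean, nfl_baseline_sd = nfl_baseline_sd,
      nfl_drift = nfl_drift,
      onl_baseline_mean = onl_baseline_mean, onl_baseline_sd = onl_baseline_sd,
      onl_drift = onl_drift,
      layer_noise_sd = layer_noise_sd, tr_margin = tr_margin,
      inter_eye_sd = inter_eye_sd,
      total_exploration_range = as.numeric(total_exploration_range),
      clamp_warn_frac = clamp_warn_frac,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Model-implied r-squared of the INL-change on DI-change regression
#'
#' Under the generative model the population coefficient of determination is
#' `a^2 s^2 / (a^2 s^2 + residual_sd^2)` with `a` the coupling slope and `s`
#' the SD of DI monthly changes.
#'
#' @param config A [cohort_config()].
#' @return A number in `[0, 1]`.
#' @export
implied_r2 <- function(config) {
  num <- (config$coupling_slope * config$di_change_sd)^2
  num / (num + config$residual_sd^2)
}

clamp <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

# exploration times realizing di exactly: t_novel + t_familiar = frac * t_total
times_for_di <- function(di, t_total, frac) {
  frac <- pmax(frac, abs(di))
  tibble(
    t_novel = t_total * (frac + di) / 2,
    t_familiar = t_total * (frac - di) / 2,
    t_total = t_total
  )
}

#' Simulate a longitudinal cohort
#'
#' Draws a cohort under the generative model described in [cohort_config()].
#' Deterministic given `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble (two eye rows per subject-age) with attribute
#'   `"schedule"`, plus attribute `"clamp_frac"`: the fraction of DI
#'   integration steps whose raw value fell outside `[-1, 1]`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  empty <- tibble(
    subject_id = character(), age_months = numeric(), eye = character(),
    nfl_gcl_ipl = numeric(), inl = numeric(), onl = numeric(), tr = numeric(),
    t_novel = numeric(), t_familiar = numeric(), t_total = numeric()
  )
  if (config$n_mice == 0) {
    attr(empty, "schedule") <- config$schedule
    attr(empty, "clamp_frac") <- 0
    return(empty)
  }

  schedule <- config$schedule
  spans <- diff(schedule)
  n_int <- length(spans)
  n_clamped <- 0L
  n_steps <- config$n_mice * n_int

  rows <- purrr::map_dfr(seq_len(config$n_mice), function(i) {
    sid <- sprintf("m%02d", i)
    g <- rnorm(n_int, config$di_change_mean, config$di_change_sd)
    di0 <- rnorm(1, config$di_baseline_mean, config$di_baseline_sd)
    traj <- di0 + cumsum(c(0, g * spans))
    # DI is bounded: keep the drawn changes intact whenever a feasible
    # trajectory exists by translating the baseline minimally into [-1, 1]
    # (a mouse whose index falls a lot simply started higher); clamp only
    # when the trajectory's range itself exceeds the scale
    if (max(traj) > 1) traj <- traj - (max(traj) - 1)
    if (min(traj) < -1) traj <- traj + (-1 - min(traj))
    di <- numeric(length(schedule))
    di[1] <- clamp(traj[1])
    for (k in seq_len(n_int)) {
      raw <- di[k] + spans[k] * g[k]
      if (raw < -1 - 1e-12 || raw > 1 + 1e-12) n_clamped <<- n_clamped + 1L
      di[k + 1] <- clamp(raw)
    }
    g_real <- diff(di) / spans
    d_inl <- config$coupling_slope * g_real + config$coupling_intercept +
      rnorm(n_int, 0, config$residual_sd)
    inl <- cumsum(c(rnorm(1, config$inl_baseline_mean, config$inl_baseline_sd),
                    d_inl * spans))
    nfl <- cumsum(c(rnorm(1, config$nfl_baseline_mean, config$nfl_baseline_sd),
                    (config$nfl_drift + rnorm(n_int, 0, config$layer_noise_sd)) * spans))
    onl <- cumsum(c(rnorm(1, config$onl_baseline_mean, config$onl_baseline_sd),
                    (config$onl_drift + rnorm(n_int, 0, config$layer_noise_sd)) * spans))
    inl <- pmax(inl, 0); nfl <- pmax(nfl, 0); onl <- pmax(onl, 0)
    tr <- nfl + inl + onl + config$tr_margin

    t_total <- runif(length(schedule), config$total_exploration_range[1],
                     config$total_exploration_range[2])
    frac <- runif(length(schedule), 0.7, 1)
    times <- times_for_di(di, t_total, frac)

    per_eye <- purrr::map_dfr(c("left", "right"), function(eye) {
      pert <- function(v) v + rnorm(length(v), 0, config$inter_eye_sd)
      nfl_e <- pmax(pert(nfl), 0)
      inl_e <- pmax(pert(inl), 0)
      onl_e <- pmax(pert(onl), 0)
      tibble(
        subject_id = sid, age_months = schedule, eye = eye,
        nfl_gcl_ipl = nfl_e, inl = inl_e, onl = onl_e,
        tr = nfl_e + inl_e + onl_e + config$tr_margin,
        t_novel = times$t_novel, t_familiar = times$t_familiar,
        t_total = times$t_total
      )
    })
    per_eye
  })

  rows <- dplyr::arrange(rows, .data$subject_id, .data$age_months, .data$eye)
  clamp_frac <- n_clamped / n_steps
  if (clamp_frac > config$clamp_warn_frac) {
    warn(sprintf(
      "DI clamped to [-1, 1] in %.1f%% of integration steps; generator parameters may be inconsistent with a bounded DI",
      100 * clamp_frac
    ))
  }
  attr(rows, "schedule") <- schedule
  attr(rows, "clamp_frac") <- clamp_frac
  rows
}

#' Deterministic reference cohort
#'
#' A constructed (not sampled) synthetic cohort of 12 mice measured at 4, 6
#' and 9 months, two eyes each, designed so that the full pipeline —
#' eye averaging, discrimination indices, the change table, threshold
#' derivation at `k = 1`, classification and contingency analysis —
#' reproduces a known set of headline numbers exactly:
#'
#' * 24 interval records whose DI monthly changes have sample mean -0.0579
#'   and SD 0.1643, hence a CI threshold of -0.2222 DI/month;
#' * an INL-change on DI-change regression line of exactly
#'   `y = 3.046 x - 0.5284` with `r^2 = 0.2970` (the residuals are
#'   constructed orthogonal to the regressor and scaled to the target
#'   residual sum of squares), hence a biomarker threshold of -1.205
#'   pixels/month;
#' * the 2x2 contingency table (tp, fn, fp, tn) = (18, 3, 0, 3), giving a
#'   two-sided Fisher p of 0.0099, sensitivity 0.8571, specificity 1.0000.
#'
#' The nuisance layer changes (NFL-GCL-IPL, ONL) are constructed orthogonal
#' to both the DI change and the INL change, so the multiple regression of
#' DI change on the three layer changes selects the INL with certainty. The
#' two eyes of each visit differ by a fixed +/-0.5 pixel offset whose sign
#' alternates across visits, so eye averaging recovers the designed values
#' exactly and the paired eye-difference test is exactly null.
#'
#' @return A cohort tibble with 72 rows (12 subjects x 3 ages x 2 eyes) and
#'   attribute `"schedule" = c(4, 6, 9)`.
#' @export
reference_cohort <- function() {
  mu <- -0.0579; sigma <- 0.1643
  a <- 3.046; b <- -0.5284; r2 <- 0.2970

  # designed standard scores of the 24 DI monthly changes: 3 below -1 (CI),
  # 3 in (-1, 0) destined for a negative test, 18 spread above
  z0 <- c(-2.2, -1.8, -1.5, -0.8, -0.6, -0.4,
          -0.30, -0.20, -0.10, 0.00, 0.05, 0.10,
          0.15, 0.20, 0.30, 0.40, 0.50, 0.60,
          0.70, 0.85, 1.00, 1.20, 1.50, 1.90)
  z <- (z0 - mean(z0)) / sd(z0)
  x <- mu + sigma * z

  # residual pattern, made orthogonal to {1, x} then scaled so the fitted
  # line and r^2 come out exactly at the designed values
  r0 <- c(-0.8, -1.0, -0.9, -1.1, -1.3, -1.5,
          0.9, -0.05, 0.45, 0.0, 0.75, 0.2,
          -0.05, 0.55, 0.1, 0.85, -0.05, 0.35,
          0.65, 0.15, 0.4, 0.7, 0.25, 0.5)
  r <- stats::residuals(lm(r0 ~ x))
  sse_target <- a^2 * sum((x - mean(x))^2) * (1 - r2) / r2
  r <- r * sqrt(sse_target / sum(r^2))
  y <- a * x + b + r

  # nuisance layer monthly changes: drift plus a pattern orthogonal to the
  # DI change, the INL change and each other
  u1 <- stats::residuals(lm(sin(seq_len(24)) ~ x + y))
  u1 <- u1 / sd(u1) * 0.3
  u3 <- stats::residuals(lm(cos(seq_len(24)) ~ x + y + u1))
  u3 <- u3 / sd(u3) * 0.3
  d_nfl <- -0.2 + u1
  d_onl <- -0.1 + u3

  # record s (1..12) is interval 4->6 of mouse s; record 12+s is 6->9
  schedule <- c(4, 6, 9)
  idx1 <- 1:12; idx2 <- 13:24
  total_drop <- 2 * x[idx1] + 3 * x[idx2]
  di4 <- 0.15 - total_drop / 2          # centres each trajectory inside [-1, 1]
  di <- cbind(di4, di4 + 2 * x[idx1], di4 + 2 * x[idx1] + 3 * x[idx2])
  integrate2 <- function(base, ch) {
    cbind(base, base + 2 * ch[idx1], base + 2 * ch[idx1] + 3 * ch[idx2])
  }
  inl <- integrate2(40 + 0.3 * ((1:12) - 6.5), y)
  nfl <- integrate2(70 + 0.4 * ((1:12) - 6.5), d_nfl)
  onl <- integrate2(60 - 0.25 * ((1:12) - 6.5), d_onl)
  tr <- nfl + inl + onl + 8

  t_total <- 40
  rows <- purrr::map_dfr(1:12, function(i) {
    purrr::map_dfr(1:3, function(v) {
      delta <- 0.5 * (-1)^(i + v)       # cancels exactly in the eye average
      purrr::map_dfr(c(left = 1, right = -1), function(sgn) {
        tibble(
          subject_id = sprintf("m%02d", i),
          age_months = schedule[v],
          eye = if (sgn > 0) "left" else "right",
          nfl_gcl_ipl = nfl[i, v] + sgn * delta,
          inl = inl[i, v] + sgn * delta,
          onl = onl[i, v] + sgn * delta,
          tr = tr[i, v] + sgn * delta,
          t_novel = t_total * (1 + di[i, v]) / 2,
          t_familiar = t_total * (1 - di[i, v]) / 2,
          t_total = t_total
        )
      })
    })
  })
  attr(rows, "schedule") <- schedule
  rows
}
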
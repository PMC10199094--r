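# small cohort builders used across test files (all generated in code)

# two mice, full 4/6/9 schedule, both eyes, hand-picked round numbers
tiny_cohort <- function() {
  grid <- expand.grid(
    subject_id = c("m1", "m2"),
    age_months = c(4, 6, 9),
    eye = c("left", "right"),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$subject_id, grid$age_months, grid$eye), ]
  n <- nrow(grid)
  base_inl <- ifelse(grid$subject_id == "m1", 40, 42)
  drop <- (grid$age_months - 4) * ifelse(grid$subject_id == "m1", 0.5, 1.5)
  eye_off <- ifelse(grid$eye == "left", 0.5, -0.5)
  di <- ifelse(grid$subject_id == "m1", 0.5 - 0.05 * (grid$age_months - 4),
               0.4 - 0.15 * (grid$age_months - 4))
  tibble::tibble(
    subject_id = grid$subject_id,
    age_months = grid$age_months,
    eye = grid$eye,
    nfl_gcl_ipl = 70 + eye_off,
    inl = base_inl - drop + eye_off,
    onl = 60 + eye_off,
    tr = 70 + base_inl - drop + 60 + 8 + eye_off,
    t_novel = 40 * (1 + di) / 2,
    t_familiar = 40 * (1 - di) / 2,
    t_total = rep(40, n)
  )
}

write_tiny_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# vectors with scipy.stats.normaltest reference values (frozen)
dago_normal50 <- c(
  0.304717079754, -1.03998410624, 0.750451195806, 0.940564716391,
  -1.95103518865, -1.30217950686, 0.127840403167, -0.316242592344,
  -0.0168011575043, -0.853043927574, 0.879397974863, 0.777791935429,
  0.0660306975612, 1.12724120697, 0.467509342252, -0.859292462883,
  0.368750784082, -0.958882600829, 0.878450301307, -0.0499259109863,
  -0.184862363545, -0.680929544404, 1.22254133867, -0.154529482069,
  -0.428327822163, -0.352133550488, 0.532309185553, 0.365444064364,
  0.412732611596, 0.430821003008, 2.14164760087, -0.406415016385,
  -0.512242729072, -0.813772728248, 0.615979422575, 1.12897229272,
  -0.113947457655, -0.840156476963, -0.824481215691, 0.650592787825,
  0.743254171203, 0.543154268305, -0.665509707289, 0.232161323067,
  0.116685809141, 0.218688596729, 0.871428777948, 0.223595548775,
  0.678913563072, 0.0675790694889
)
dago_normal50_k2 <- 0.7077942560
dago_normal50_p <- 0.7019471744

dago_exp30 <- c(
  0.167356396116, 1.31505684455, 3.99575627118, 0.563538092389,
  0.284039701601, 0.397756253907, 0.361342222935, 0.129633603224,
  1.08332513487, 1.37584885352, 1.50780913064, 5.30988279576,
  2.10666023478, 1.6448658405, 1.04349148198, 0.592524198961,
  0.0444535562718, 0.95660278682, 0.621383087493, 1.50796137511,
  2.02800158116, 0.332068814697, 0.0497507212037, 0.924822235123,
  2.55341939979, 0.821071596608, 2.13094288584, 0.75301474534,
  1.31399404764, 0.288782994684
)
dago_exp30_k2 <- 23.4343555499
dago_exp30_p <- 0.0000081526

dago_t12 <- c(
  0.729676068314, -0.863652484768, -0.529188632554, 0.382611855178,
  -0.498248151022, -3.60417138287, 0.741103735311, 1.75441676067,
  -1.16791075919, -0.272024306151, 0.442958919826, -1.58641232558
)
dago_t12_k2 <- 4.2332845885
dago_t12_p <- 0.1204353368

# a 24-vector with exact sample mean -0.0579 and exact sample SD 0.1643,
# built by affine standardization of an arbitrary spread
di_changes_exact <- function(mu = -0.0579, sigma = 0.1643) {
  z <- seq(-2, 2, length.out = 24)
  z <- (z - mean(z)) / sd(z)
  mu + sigma * z
}

# brute-force normal-equations OLS oracle (independent of lm)
ols_oracle <- function(X, y) {
  X <- cbind(1, X)
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  n <- nrow(X); p <- ncol(X) - 1
  s2 <- sum(resid^2) / (n - p - 1)
  covb <- s2 * solve(xtx)
  se <- sqrt(diag(covb))
  tstat <- beta / se
  list(
    beta = drop(beta), se = se,
    p = 2 * pt(abs(drop(tstat)), n - p - 1, lower.tail = FALSE),
    ss_resid = sum(resid^2),
    covb = covb
  )
}
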
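# Probabilistic rib fracture risk: per-rib strain -> per-rib fracture
# probability via an age-adjusted log-normal probit risk function, then
# aggregation to NFR2+ (probability of two or more fractured ribs) under
# independence across ribs.

#' Age-adjusted strain-based rib fracture risk function
#'
#' Log-normal probit form: `p = Phi((ln eps - (b0 + b_age * age)) / sigma)`.
#' The default coefficients are documented placeholders chosen to give a
#' plausible strain scale (median fracture strain about 2% engineering
#' strain at age 45, decreasing with age); users should supply published
#' coefficients for quantitative work.
#'
#' @param b0 Intercept of the log-strain threshold.
#' @param b_age Age slope (per year); must be <= 0 so risk is non-decreasing
#'   in age.
#' @param sigma Log-strain scale, > 0.
#' @param age_default Default occupant age, years.
#' @return Object of class `"risk_function"`.
#' @export
risk_function <- function(b0 = -3.687, b_age = -0.005, sigma = 0.25,
                          age_default = 45) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (b_age > 0) stop("b_age must be <= 0 (risk non-decreasing in age)",
                      call. = FALSE)
  structure(list(form = "lognormal_probit", b0 = b0, b_age = b_age,
                 sigma = sigma, age_default = age_default),
            class = "risk_function")
}

#' Write / read a risk-function configuration (JSON)
#'
#' @param rf A [risk_function()].
#' @param path File path.
#' @return `read_risk_function()` returns a `"risk_function"`.
#' @export
write_risk_function <- function(rf, path) {
  jsonlite::write_json(list(form = rf$form, b0 = rf$b0, b_age = rf$b_age,
                            sigma = rf$sigma, age_default = rf$age_default),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_function
#' @export
read_risk_function <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_function(cfg$b0, cfg$b_age, cfg$sigma, cfg$age_default)
}

#' Per-rib fracture probability from peak strain
#'
#' Vectorized over strain; strains below 1e-12 map to probability 0 (the
#' log-strain threshold form is undefined at zero strain).
#'
#' @param strain Non-negative engineering strain (vector).
#' @param age Occupant age in years, in (0, 120).
#' @param rf A [risk_function()].
#' @return Fracture probabilities in \[0, 1\].
#' @export
rib_fracture_probability <- function(strain, age = rf$age_default,
                                     rf = risk_function()) {
  if (any(strain < 0)) stop("strain must be non-negative", call. = FALSE)
  if (!(age > 0 && age < 120)) stop("age must be in (0, 120)", call. = FALSE)
  p <- numeric(length(strain))
  ok <- strain >= 1e-12
  p[ok] <- pnorm((log(strain[ok]) - (rf$b0 + rf$b_age * age)) / rf$sigma)
  p
}

#' Probability of two or more fractured ribs (NFR2+)
#'
#' Assuming independent rib fractures, the number of fractured ribs is
#' Poisson-binomial; NFR2+ = 1 - P(0 fractures) - P(1 fracture). P(0) and
#' P(1) are accumulated by the stable two-state recursion over ribs, which
#' handles probabilities at exactly 0 and 1.
#'
#' @param p Vector of per-rib fracture probabilities in \[0, 1\].
#' @return NFR2+ probability.
#' @examples
#' nfr2plus(c(0.5, 0.5, rep(0, 22)))  # 0.25
#' @export
nfr2plus <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) {
    stop("fracture probabilities must lie in [0, 1]", call. = FALSE)
  }
  p0 <- 1; p1 <- 0
  for (pi in p) {
    p1 <- p1 * (1 - pi) + p0 * pi
    p0 <- p0 * (1 - pi)
  }
  max(0, min(1, 1 - p0 - p1))
}

#' Brute-force NFR2+ by outcome enumeration (validation oracle)
#'
#' Sums the probabilities of all 2^n fracture-outcome bitmasks with two or
#' more fractures. Refuses n > 20 (combinatorial guard). Independent of the
#' closed-form recursion in [nfr2plus()].
#'
#' @param p Vector of per-rib fracture probabilities, length <= 20.
#' @return NFR2+ probability.
#' @export
nfr2plus_bruteforce <- function(p) {
  n <- length(p)
  if (n > 20) stop("refusing enumeration for n > 20", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  m <- 2^n
  prob <- rep(1, m)
  count <- integer(m)
  ids <- 0:(m - 1)
  for (j in seq_len(n)) {
    frac <- bitwAnd(ids, bitwShiftL(1L, j - 1L)) > 0
    prob <- prob * ifelse(frac, p[j], 1 - p[j])
    count <- count + frac
  }
  sum(prob[count >= 2])
}

#' Per-rib risks and NFR2+ for a strain result
#'
#' @param strain A `"strain_result"` or a numeric vector of per-rib strains.
#' @param age Occupant age, years.
#' @param rf A [risk_function()].
#' @return Object of class `"risk_result"`: `p` (per-rib probabilities),
#'   `nfr2plus`, `age`, `load_case`.
#' @export
risk_result <- function(strain, age = rf$age_default, rf = risk_function()) {
  case <- if (inherits(strain, "strain_result")) strain$load_case else NA
  eps <- if (inherits(strain, "strain_result")) strain$epsilon else
    as.numeric(strain)
  p <- rib_fracture_probability(eps, age, rf)
  structure(list(p = p, nfr2plus = nfr2plus(p), age = age, load_case = case),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Risk result (%s, age %g): NFR2+ = %.4f\n",
              x$load_case %||% "unnamed case", x$age, x$nfr2plus))
  cat(sprintf("  per-rib fracture probability: max %.4f, mean %.4f\n",
              max(x$p), mean(x$p)))
  invisible(x)
}

#' Write per-rib risks plus the NFR2+ summary row as CSV
#'
#' @param risk A `"risk_result"`.
#' @param strain The matching `"strain_result"` (for the strain column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(risk, strain, path) {
  eps <- if (inherits(strain, "strain_result")) strain$epsilon else
    as.numeric(strain)
  df <- data.frame(case = risk$load_case %||% "case",
                   rib_index = seq_along(risk$p),
                   strain = eps, p = risk$p)
  summary_row <- data.frame(case = risk$load_case %||% "case",
                            rib_index = NA_integer_,
                            strain = NA_real_, p = risk$nfr2plus)
  write.csv(rbind(df, summary_row), path, row.names = FALSE)
  invisible(path)
}
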
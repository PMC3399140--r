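# Temperature-driven exponential carcass decomposition.
#
# Dry mass decays as W_t = W_0 * exp(k * t) with k <= 0 (day^-1); k is
# estimated from paired mass observations as k = ln(W_t/W_0)/t and modelled
# as a linear function of air temperature fitted to published salmonid
# decay observations.

#' Published salmonid carcass decay observations
#'
#' Nine literature-compiled observations of the daily exponential
#' decomposition rate `k` (day^-1, negative = mass loss) of chum salmon,
#' pink salmon, and rainbow trout carcasses at known temperatures, in air
#' or under water. These are the observations the temperature-decay
#' regression is fitted to.
#'
#' @param path CSV file to read; defaults to the copy shipped with the
#'   package. Schema: `species,temperature_C,k_per_day,exposure,source`.
#' @return data.frame with columns `species`, `temperature_C`, `k_per_day`,
#'   `exposure`, `source`.
#' @export
decay_observations <- function(path = system.file("extdata", "decay_observations.csv",
                                                  package = "eaglewinter")) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "temperature_C", "k_per_day", "exposure", "source")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("decay observations: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(obs$k_per_day > 0)) {
    stop("decay observations: k must be <= 0 (mass loss)")
  }
  obs
}

#' Decay rate from paired dry-mass observations
#'
#' `k = ln(w_t / w_0) / t`, the per-day exponential rate of dry-mass change.
#' Mass loss gives a negative value.
#'
#' @param w0 Dry mass at time zero (> 0).
#' @param wt Dry mass after `t` days (> 0).
#' @param t Elapsed time, days (> 0).
#' @return k, day^-1.
#' @export
decay_rate_from_masses <- function(w0, wt, t) {
  if (any(w0 <= 0) || any(wt <= 0)) stop("masses must be > 0")
  if (any(t <= 0)) stop("elapsed time must be > 0")
  log(wt / w0) / t
}

#' Fit the linear temperature -> decay-rate model
#'
#' Ordinary least squares of `k_per_day` on `temperature_C`, pooling air and
#' water exposures.
#'
#' @param obs data.frame with columns `temperature_C` and `k_per_day`, e.g.
#'   from [decay_observations()]. At least two observations at two distinct
#'   temperatures are required.
#' @return A `decay_model`: list with `slope` (day^-1 C^-1), `intercept`
#'   (day^-1), `r_squared`, `n_obs`.
#' @export
fit_decay_model <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("temperature_C", "k_per_day") %in% names(obs)))
  if (nrow(obs) < 2L) stop("need at least 2 observations")
  if (length(unique(obs$temperature_C)) < 2L) {
    stop("singular fit: all temperatures identical")
  }
  fit <- stats::lm(k_per_day ~ temperature_C, data = obs)
  s <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)["temperature_C"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = s$r.squared,
    n_obs = nrow(obs)
  ), class = "decay_model")
}

#' Construct a decay model from known coefficients
#'
#' @param slope day^-1 C^-1; `intercept` day^-1.
#' @param intercept,r_squared,n_obs See [fit_decay_model()].
#' @export
decay_model <- function(slope, intercept, r_squared = NA_real_, n_obs = NA_integer_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_obs = n_obs),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> k = %.4f + %.4f * T  (r^2 = %.2f, n = %s)\n",
              x$intercept, x$slope, x$r_squared, x$n_obs))
  invisible(x)
}

#' Predict the daily decay rate at a temperature
#'
#' Evaluates the fitted line `slope * T + intercept`, clamped at zero:
#' decomposition can stall in the cold but never adds mass.
#'
#' @param model A `decay_model`.
#' @param temperature Air temperature, degrees C (vectorized).
#' @return k, day^-1, always <= 0.
#' @export
predict_k <- function(model, temperature) {
  stopifnot(inherits(model, "decay_model"))
  pmin(0, model$slope * temperature + model$intercept)
}

#' Apply exponential decay to a dry mass
#'
#' `mass * exp(k * days)`. Daily application compounds exactly: applying one
#' day at a time equals a single multi-day application for constant `k`.
#'
#' @param mass Dry mass, kg (>= 0).
#' @param k Decay rate, day^-1 (<= 0).
#' @param days Elapsed days (>= 0).
#' @return Decayed dry mass, kg.
#' @export
apply_decay <- function(mass, k, days) {
  if (any(mass < 0)) stop("mass must be >= 0")
  if (any(k > 0)) stop("k must be <= 0 (decay cannot add mass)")
  if (any(days < 0)) stop("days must be >= 0")
  mass * exp(k * days)
}

#' Serialize / deserialize a fitted decay model
#'
#' Plain-text `key: value` format (DCF) holding slope, intercept,
#' r_squared and n_obs.
#'
#' @param model A `decay_model`; `path` a file path.
#' @param path File path.
#' @return `read_decay_model` returns a `decay_model`.
#' @export
write_decay_model <- function(model, path) {
  stopifnot(inherits(model, "decay_model"))
  df <- data.frame(slope = format(model$slope, digits = 17),
                   intercept = format(model$intercept, digits = 17),
                   r_squared = format(model$r_squared, digits = 17),
                   n_obs = model$n_obs)
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_decay_model
#' @export
read_decay_model <- function(path) {
  df <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  decay_model(slope = as.numeric(df$slope),
              intercept = as.numeric(df$intercept),
              r_squared = as.numeric(df$r_squared),
              n_obs = as.integer(df$n_obs))
}
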
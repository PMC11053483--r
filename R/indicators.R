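# Gait-health indicators: cadence / walking speed, symmetry index, balance
# score, normalized signal energy, and initial-contact-type classification.

#' Cadence from a 10-second window
#'
#' Counts footsteps within a 10 s window: `n10` footsteps give a step
#' frequency of `n10 / 10` steps/s and a cadence of `6 * n10` steps/min.
#' When the trace is shorter than the window, the footstep rate over the
#' available span (events minus one, over the span) is scaled to a 10 s
#' equivalent and the result flagged as extrapolated.
#'
#' @param events a `footstep_events` data.frame (or anything with a
#'   `peak_time` column).
#' @param window_start start of the window in seconds (default the first
#'   event).
#' @param trace_end end of the usable trace; defaults to the last event time.
#' @return list of class `cadence_result`: `n10`, `step_frequency` (steps/s),
#'   `cadence` (steps/min), `partial_window` (logical flag).
#' @export
cadence_from_window <- function(events, window_start = NULL,
                                trace_end = NULL) {
  pt <- events$peak_time
  window_start <- window_start %||% if (length(pt)) pt[1] else 0
  trace_end <- trace_end %||% if (length(pt)) pt[length(pt)] else window_start
  avail <- trace_end - window_start
  partial <- avail < 10
  n_in <- sum(pt >= window_start & pt <= window_start + 10)
  # short traces: extrapolate from the inter-event rate ((n-1) gaps span
  # the available window), flagged as partial
  n10 <- if (partial && avail > 0 && n_in > 1) (n_in - 1) * 10 / avail
         else n_in
  structure(list(n10 = n10, step_frequency = n10 / 10, cadence = 6 * n10,
                 partial_window = partial), class = "cadence_result")
}

#' Walking speed of one step
#'
#' Step length divided by step time: `v_i = l_i / (t_{i+1}^s - t_i^s)`.
#'
#' @param step_length metres (vectorized).
#' @param t_strike,t_strike_next strike times of consecutive footsteps.
#' @return speed in m/s.
#' @examples
#' walking_speed(0.5, 0, 0.5) # 1 m/s
#' @export
walking_speed <- function(step_length, t_strike, t_strike_next) {
  if (any(t_strike_next <= t_strike))
    stop("strike times must be increasing", call. = FALSE)
  step_length / (t_strike_next - t_strike)
}

#' Absolute symmetry index
#'
#' `SI = 2 |X_R - X_L| / (X_R + X_L)`, in [0, 2]. The index uses the absolute
#' left-right difference, so it does not require knowing which detected side
#' is truly the left foot.
#'
#' @param x_left,x_right non-negative per-side measures (e.g. trace means of
#'   stance time, step length or normalized energy grouped by side parity).
#' @param measure_name optional label.
#' @return list of class `symmetry_result`: `measure_name`, `x_left`,
#'   `x_right`, `si`.
#' @examples
#' symmetry_index(0.60, 0.75)$si # 0.2222...
#' @export
symmetry_index <- function(x_left, x_right, measure_name = NA_character_) {
  if (x_left < 0 || x_right < 0)
    stop("symmetry measures must be non-negative", call. = FALSE)
  if (x_left + x_right == 0)
    stop("symmetry index undefined when both sides are zero", call. = FALSE)
  si <- 2 * abs(x_right - x_left) / (x_right + x_left)
  structure(list(measure_name = measure_name, x_left = x_left,
                 x_right = x_right, si = si), class = "symmetry_result")
}

#' Balance score
#'
#' Mean squared relative deviation of per-footstep measures from their trace
#' mean: `BS = (1/N) * sum_i ((X_i - mean(X)) / mean(X))^2`. Zero iff all
#' measures are equal; invariant to positive rescaling of X.
#'
#' @param x per-footstep measures (N >= 2, non-zero mean).
#' @param measure_name optional label.
#' @return list of class `balance_result`: `measure_name`, `n`, `bs`.
#' @examples
#' balance_score(c(0.4, 0.6))$bs # 0.04
#' @export
balance_score <- function(x, measure_name = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 footsteps", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("balance score undefined for zero-mean measures",
                   call. = FALSE)
  bs <- mean(((x - m) / m)^2)
  structure(list(measure_name = measure_name, n = length(x), bs = bs),
            class = "balance_result")
}

#' Distance-normalized signal energy
#'
#' Signal energy of a footstep window compensated for wave attenuation:
#' `E_norm = sum(x^2) * exp(alpha * d)`, with `alpha` the floor's amplitude
#' attenuation rate (1/m) and `d` the footstep-to-sensor distance. With the
#' correct `alpha`, the normalized energy of one footstep agrees across
#' sensors at different distances, making it a proxy for the ground reaction
#' force magnitude.
#'
#' @param x samples of the footstep window (one channel).
#' @param d footstep-to-sensor distance in metres (>= 0).
#' @param alpha attenuation rate in 1/m. Note the amplitude decays as
#'   `exp(-alpha d)` so energy decays as `exp(-2 alpha d)`; pass
#'   `2 * alpha_amplitude` to fully undo it, or the energy-scale rate
#'   directly.
#' @return normalized energy (signal units squared).
#' @export
normalized_energy <- function(x, d, alpha) {
  if (length(x) == 0) stop("empty footstep window", call. = FALSE)
  if (d < 0) stop_field("d", "must be >= 0")
  sum(x^2) * exp(alpha * d)
}

#' Frequency-bin contact features
#'
#' Divides the frequency axis into 10 Hz bins up to `f_max` and, for each
#' bin, averages the time-summed wavelet magnitudes of the footstep window;
#' the vector is normalized by its total so classification is invariant to
#' signal amplitude (and hence footstep-to-sensor distance).
#'
#' @param spectrum a `wavelet_spectrum` covering the footstep.
#' @param window `c(t0, t1)` footstep window in seconds.
#' @param f_max top of the feature range in Hz (default 500, the
#'   temporal-path lowpass cutoff, giving 50 features).
#' @return named numeric vector of bin features (`bin_0_10`, ...).
#' @export
contact_features <- function(spectrum, window, f_max = 500) {
  cols <- which(spectrum$time >= window[1] & spectrum$time <= window[2])
  if (length(cols) < 2) stop("footstep window too short", call. = FALSE)
  tsum <- rowSums(spectrum$magnitude[, cols, drop = FALSE])
  edges <- seq(0, f_max, by = 10)
  nb <- length(edges) - 1
  feat <- numeric(nb)
  for (b in seq_len(nb)) {
    rows <- which(spectrum$freq > edges[b] & spectrum$freq <= edges[b + 1])
    feat[b] <- if (length(rows)) mean(tsum[rows]) else 0
  }
  names(feat) <- sprintf("bin_%d_%d", edges[-length(edges)], edges[-1])
  tot <- sum(feat)
  if (tot > 0) feat <- feat / tot
  feat
}

#' Train the initial-contact-type classifier
#'
#' One-vs-rest support vector machines with a Gaussian (RBF) kernel on
#' standardized frequency-bin features; per-class decision margins are mapped
#' to probabilities with a unit-temperature softmax at prediction time.
#'
#' @param features numeric matrix (footsteps x bins).
#' @param labels factor or character vector of contact types (>= 2 classes).
#' @param cost,gamma SVM hyperparameters; `gamma` defaults to `1 / n_bins`.
#' @return an object of class `contact_classifier` (models, scaling
#'   statistics, classes, training metadata).
#' @export
train_contact_classifier <- function(features, labels, cost = 1,
                                     gamma = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("need at least two contact classes to train", call. = FALSE)
  center <- colMeans(features)
  scale_ <- apply(features, 2, sd)
  scale_[scale_ == 0] <- 1
  z <- scale(features, center, scale_)
  gamma <- gamma %||% (1 / ncol(features))
  models <- lapply(setNames(nm = classes), function(cl) {
    y <- factor(ifelse(labels == cl, "yes", "no"), levels = c("yes", "no"))
    e1071::svm(z, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
  })
  structure(list(models = models, center = center, scale = scale_,
                 classes = classes,
                 meta = list(n_train = nrow(features), cost = cost,
                             gamma = gamma, version = "1",
                             trained = format(Sys.time(), "%Y-%m-%d"))),
            class = "contact_classifier")
}

#' Predict initial-contact-type probabilities
#'
#' @param model a [train_contact_classifier()] result.
#' @param features numeric matrix (footsteps x bins) on the training feature
#'   layout.
#' @return data.frame: one probability column per class (rows sum to 1) and
#'   a `predicted` column (argmax class).
#' @export
predict_contact <- function(model, features) {
  features <- as.matrix(features)
  z <- scale(features, model$center, model$scale)
  scores <- vapply(model$classes, function(cl) {
    p <- predict(model$models[[cl]], z, decision.values = TRUE)
    dv <- drop(attr(p, "decision.values"))
    # orient margins so positive always means "this class"
    if (grepl("^yes", colnames(attr(p, "decision.values"))[1])) dv else -dv
  }, numeric(nrow(z)))
  scores <- matrix(scores, ncol = length(model$classes),
                   dimnames = list(NULL, model$classes))
  ex <- exp(scores - apply(scores, 1, max))
  probs <- ex / rowSums(ex)
  out <- as.data.frame(probs)
  out$predicted <- model$classes[apply(probs, 1, which.max)]
  out
}

#' Persist / restore a contact classifier
#'
#' The model is stored with its training metadata (feature scaling, classes,
#' hyperparameters, version) so later predictions reproduce the training
#' standardization.
#'
#' @param model a `contact_classifier`.
#' @param path file path (`.rds`).
#' @export
save_contact_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_contact_classifier
#' @export
load_contact_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "contact_classifier"))
    stop("file does not contain a contact classifier", call. = FALSE)
  m
}

#' Simulate a labelled initial-contact-type dataset
#'
#' Generates single-footstep vibration records (one sensor at a randomized
#' distance, randomized stance duration, force amplitude and noise draw) for
#' each contact type and returns their frequency-bin feature vectors, ready
#' for [train_contact_classifier()].
#'
#' @param n_per_class footsteps per contact type.
#' @param floor a [floor_model()].
#' @param sample_rate Hz.
#' @param snr_db per-record SNR in dB (active-span RMS definition).
#' @param seed RNG seed.
#' @return list: `features` (matrix), `labels` (character vector).
#' @export
simulate_contact_dataset <- function(n_per_class = 200,
                                     floor = floor_preset("concrete"),
                                     sample_rate = 1000, snr_db = 20,
                                     seed = 1) {
  set.seed(seed)
  types <- c("heel", "midfoot", "toe")
  n <- n_per_class * length(types)
  labels <- rep(types, each = n_per_class)
  stance <- pmax(rnorm(n, 0.72, 0.06), 0.4)
  dist <- runif(n, 0.8, 3)
  amp <- exp(rnorm(n, 0, 0.2))
  noise_seeds <- sample.int(1e7, n)
  freqs <- seq(5, 495, by = 5)
  feats <- NULL
  lay <- sensor_layout("S1", 0, 0)
  for (i in seq_len(n)) {
    truth <- data.frame(step = 1L, side = "A", t_strike = 0.5,
                        t_off = 0.5 + stance[i], x = dist[i], y = 0,
                        contact_type = labels[i], stringsAsFactors = FALSE)
    clean <- simulate_record(floor, truth, lay, sample_rate,
                             duration = 0.5 + stance[i] + 0.6,
                             amplitude = amp[i])
    tm <- rec_times(clean)
    act <- tm >= 0.5 & tm <= 0.5 + stance[i]
    noise_sd <- sqrt(mean(clean$samples[act, 1]^2)) / 10^(snr_db / 20)
    set.seed(noise_seeds[i])
    rec <- clean
    rec$samples <- clean$samples + rnorm(length(clean$samples), 0, noise_sd)
    sp <- morlet_cwt(rec$samples[, 1], sample_rate, freqs, times = tm)
    f <- contact_features(sp, c(0.4, 0.5 + stance[i] + 0.15))
    feats <- rbind(feats, f)
  }
  rownames(feats) <- NULL
  list(features = feats, labels = labels)
}
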
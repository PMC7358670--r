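# Independent oracles and small fixture builders shared across tests.

# Exhaustive Otsu oracle: for every candidate threshold t in 1..255
# (background = {< t}, foreground = {>= t}) compute the between-class
# variance directly from the class moments; return the lowest argmax.
# Deliberately naive (double loop over thresholds) and independent of
# the package's cumulative-sum implementation.
otsu_brute_force <- function(pixels) {
  v <- as.integer(pixels)
  best_t <- NA_integer_
  best_var <- -Inf
  n <- length(v)
  for (t in 1:255) {
    bg <- v[v < t]
    fg <- v[v >= t]
    if (!length(bg) || !length(fg)) next
    w0 <- length(bg) / n
    w1 <- length(fg) / n
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best_var + 1e-12) {
      best_var <- bcv
      best_t <- t
    }
  }
  best_t
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Smear observation rows for one sample.
make_obs <- function(sample_id, n_vac, counts, n_counted = 100L) {
  data.frame(sample_id = sample_id,
             observer_id = seq_along(n_vac),
             n_counted = n_counted, n_vacuolated = n_vac,
             vacuole_counts = counts, stringsAsFactors = FALSE)
}

# Small three-class config used by several recovery tests.
small_config <- function(seed = 1L, ...) {
  cohort_config(n_patients_per_class = c(control = 4, protracted = 4,
                                         classical = 4),
                samples_per_patient = c(2L, 3L), seed = seed, ...)
}
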
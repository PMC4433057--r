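# Shared fixtures: all synthetic, built in code at test time.

CATALOG <- load_catalog()

noise_free <- function(...) {
  args <- list(gyro_noise_sd = 0, accel_noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(noise_model, args)
}

# static stream at a fixed true orientation (sensor-to-world q)
static_stream <- function(q = c(1, 0, 0, 0), duration = 2, rate = 100,
                          noise = noise_free(), site_id = "test") {
  n <- round(duration * rate) + 1L
  tr <- orientation_trace(seq(0, duration, by = 1 / rate),
                          matrix(rep(q, n), ncol = 4, byrow = TRUE))
  synthesize_imu(tr, noise, site_id = site_id)
}

# one noise-free repetition of an examination, measured end to end
measure_examination <- function(angle_id, peak, start_deg = 0,
                                mounting = NULL, rate = 50,
                                noise = noise_free(),
                                catalog = CATALOG) {
  exam <- lookup_examination(catalog, angle_id)
  script <- motion_script(angle_id, peaks = peak, start_deg = start_deg,
                          sampling_rate = rate)
  kin <- simulate_segment_kinematics(script, exam, catalog)
  streams <- lapply(stats::setNames(nm = names(kin$repetitions[[1]]$traces)),
                    function(site) {
                      m <- if (!is.null(mounting) && site %in% names(mounting))
                        mounting[[site]] else c(1, 0, 0, 0)
                      synthesize_imu(kin$repetitions[[1]]$traces[[site]],
                                     noise, site_id = site, mounting = m)
                    })
  rec <- list(angle_id = angle_id,
              repetitions = list(list(rep = 1L, streams = streams)))
  process_recording(rec, catalog, mounting = mounting)
}

random_unit_quat <- function(n = 1) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  if (n == 1) q[1, ] else q
}

# independent ICC(3,k) oracle: two-way ANOVA via stats::aov, a different
# route than the package's closed-form mean squares
icc_3k_oracle <- function(m) {
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  (ms[1] - ms[3]) / ms[1]
}
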
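# Shared in-code fixtures for the test suite.

# A deterministic sinusoidal recording with known content.
sine_recording <- function(freq_hz, fs = BONN_FS, duration_s = 4,
                           amplitude = 1, label = "Z", id = "sine") {
  t <- (0:(round(duration_s * fs) - 1)) / fs
  recording(amplitude * sin(2 * pi * freq_hz * t), fs = fs,
            label = label, source_id = id)
}

# A bare epoch wrapper for feature tests.
make_epoch <- function(samples, fs = 100, label = "Z", id = "ep",
                       window_s = length(samples) / fs) {
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 source_id = id, window_s = window_s, start_index = 0L),
            class = "eeg_epoch")
}

# Tiny Bonn-dialect directory tree: `files_per_class` files per class,
# `n` integer samples each. Returns the root path.
write_tiny_bonn_tree <- function(root, files_per_class = 2, n = 32,
                                 classes = BONN_CLASSES) {
  for (cl in classes) {
    d <- file.path(root, cl)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(files_per_class)) {
      writeLines(as.character(seq_len(n) * (i + match(cl, BONN_CLASSES))),
                 file.path(d, sprintf("%s%03d.txt", cl, i)))
    }
  }
  root
}

# A linearly separable 3-class feature table mapped onto Z/O/N labels:
# class centroids far apart relative to the noise.
separable_toy_table <- function(n_per_class = 50, seed = 42) {
  withr::with_seed(seed, {
    centroids <- rbind(c(0, 0), c(6, 0), c(0, 6))
    labels <- c("Z", "O", "N")
    X <- do.call(rbind, lapply(1:3, function(k) {
      cbind(rnorm(n_per_class, centroids[k, 1], 0.4),
            rnorm(n_per_class, centroids[k, 2], 0.4))
    }))
    data.frame(x1 = X[, 1], x2 = X[, 2],
               label = factor(rep(labels, each = n_per_class),
                              levels = labels))
  })
}
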
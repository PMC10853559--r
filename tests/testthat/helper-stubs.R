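# a boundary classifier stub whose positive-class probability is fixed:
# zeroed convolutions leave only batch-norm offsets, and the output bias
# carries the desired logit margin
stub_classifier <- function(p_positive, netcfg) {
  ns <- asNamespace("fingertap")
  set.seed(1)
  params <- ns$nn_init(netcfg)
  for (nm in names(params)) params[[nm]][] <- 0
  logit <- log(p_positive / (1 - p_positive))
  params[["fc.b"]] <- c(0, logit)
  structure(
    list(params = params, state = ns$nn_state_init(netcfg), netcfg = netcfg,
         tcfg = NULL, fold_mcc = NA_real_, mean_mcc = NA_real_, best_fold = 1L),
    class = "binary_tap_classifier"
  )
}

stub_scorer <- function(p1, p2, p3, netcfg = network_config(input_length = 30L,
                                                            channels = c(4L, 4L),
                                                            dilations = c(1L, 2L),
                                                            stride = 2L)) {
  pol <- augment_policy("training", crop_length = 60L, n_crops = 1, n_rotations = 1,
                        crop_sigma_frac = 0)
  structure(
    list(classifiers = list(`1` = stub_classifier(p1, netcfg),
                            `2` = stub_classifier(p2, netcfg),
                            `3` = stub_classifier(p3, netcfg)),
         boundaries = 1:3, netcfg = netcfg, tcfg = NULL, policy = pol,
         n_clips = 0L, class_counts = table(factor(integer(0), levels = 0:3))),
    class = "tap_scorer"
  )
}

small_task <- function(n_per_class = 12, seed = 3) {
  # two well-separated tapping phenotypes: brisk large taps vs slow small
  # taps with decrement -> linearly separable for any sane classifier
  with_seed_draw(seed, {
    out <- list()
    k <- 0
    for (cl in 0:1) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1
        cfg <- tap_sim_config(
          duration_s = 4, fps = 30,
          base_frequency = if (cl == 0) 4 else 1.2,
          base_amplitude = if (cl == 0) 0.3 else 0.08,
          decrement_rate = if (cl == 0) 0 else 0.1,
          jitter_sd = 0.01
        )
        sim <- simulate_clip(cfg, subject_id = sprintf("T%03d", k))
        out[[k]] <- labeled_clip(sim$clip, item_score = cl * 2,
                                 subject_id = sprintf("T%03d", k))
      }
    }
    out
  })
}

tiny_net <- function() {
  network_config(input_length = 40L, channels = c(8L, 16L), kernel = 3L,
                 dilations = c(1L, 2L), stride = 2L)
}

tiny_train <- function(epochs = 12, seed = 5) {
  train_config(batch_size = 8L, epochs = epochs, seed = seed,
               augment = augment_policy("training", crop_length = 80L,
                                        rotation_range = 15, seed = seed))
}
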
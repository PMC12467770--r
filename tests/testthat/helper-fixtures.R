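# Shared fixtures, all generated in code at test time.

# fast MINE settings for mechanics-level tests (not estimator-quality tests)
quick_mine_cfg <- function(n_seeds = 1L) {
  mine_train_config(batch_size = 50L, max_epochs = 6L, plateau_patience = 3L,
                    n_seeds = n_seeds)
}

quick_net_cfg <- function() statistics_net_config(hidden_sizes = c(16L, 8L))

# tiny rendered dataset shared across representation/pipeline tests
tiny_image_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- sample_cohort(cohort_config(n = 120L, seed = 77L))
      imgs <- render_images(coh, render_config(size = 64L), seed = 78L)
      cache <<- list(cohort = coh, images = imgs)
    }
    cache
  }
})

tiny_conv_model <- function(seed = 1L, base_width = 4L) {
  build_backbone(backbone_config("conv", input_size = 64L,
                                 base_width = base_width), seed = seed)
}
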
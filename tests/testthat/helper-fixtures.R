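# Shared fixtures: all tiny and generated in code.

tiny_spec <- function(...) {
  phantom_spec(extent_mm = c(64, 48, 48), ...)
}

tiny_preproc <- function() {
  preproc_config(target_spacing = c(1, 1, 2), crop_shape = c(64L, 48L, 24L))
}

# a small random binary mask
rand_mask <- function(dim3, p = 0.3) {
  array(stats::rbinom(prod(dim3), 1, p), dim = dim3)
}

# brute-force voxel-count metrics, computed by explicit iteration
oracle_counts <- function(pred, gt) {
  np <- 0L; ng <- 0L; ni <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] != 0) np <- np + 1L
    if (gt[i] != 0) ng <- ng + 1L
    if (pred[i] != 0 && gt[i] != 0) ni <- ni + 1L
  }
  list(np = np, ng = ng, ni = ni)
}

# a unet model whose output probabilities are ~0 everywhere (all head
# biases strongly negative), for localization-failure paths
empty_output_model <- function(cfg) {
  m <- build_unet(cfg, seed = 1)
  for (nm in names(m$params)) {
    if (grepl("^(head|ds[0-9]+)_b$", nm)) {
      m$params[[nm]] <- rep(-20, length(m$params[[nm]]))
    }
  }
  m
}
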
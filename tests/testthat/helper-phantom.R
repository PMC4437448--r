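# Shared fixtures and independent oracles, all built in code at test time.

paper_echo_times <- seq(18, 216, by = 18)

# small, fast noiseless phantom for structural tests
small_phantom <- function(...) {
  generate_phantom(phantom_spec(matrix = 48L, n_slices = 4L,
                                noise_model = "none", ...))
}

# independent volumetry oracle: area per slice summed, times slice thickness
region_volume_oracle <- function(mask, region, geometry) {
  codes <- mask$legend[[region]]
  hier <- switch(region,
    hemisphere_ipsi = c("hemisphere_ipsi", "lesion", "roi_ischemic"),
    hemisphere_contra = c("hemisphere_contra", "roi_contralateral"),
    lesion = c("lesion", "roi_ischemic"),
    region)
  codes <- unname(mask$legend[intersect(hier, names(mask$legend))])
  dims <- dim(mask$labels)
  total <- 0
  for (k in seq_len(dims[3])) {
    n_k <- sum(mask$labels[, , k] %in% codes)
    area_k <- n_k * geometry$in_plane_spacing^2
    total <- total + area_k * (geometry$slice_thickness + geometry$slice_gap)
  }
  total
}

# brute-force Mann-Whitney oracle: enumerate every assignment of ranks to
# group 1 and count assignments with |U - n1*n2/2| at least the observed
mann_whitney_enum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  u_all <- apply(subsets, 2L, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  m <- n1 * n2 / 2
  mean(abs(u_all - m) >= abs(u_obs - m) - 1e-9)
}

# random two-hemisphere label mask for volumetry property tests
random_label_mask <- function(dims = c(12L, 10L, 3L), geometry,
                              p_lesion = 0.3) {
  legend <- default_legend()
  labels <- array(0L, dims)
  nx <- dims[1]
  mid <- (nx + 1) / 2
  left <- seq_len(floor(mid - 0.5))
  right <- seq.int(ceiling(mid + 0.5), nx)
  for (k in seq_len(dims[3])) {
    labels[left, , k][runif(length(left) * dims[2]) < 0.7] <-
      legend[["hemisphere_contra"]]
    sl <- labels[right, , k]
    u <- runif(length(sl))
    sl[u < 0.7] <- legend[["hemisphere_ipsi"]]
    sl[u < 0.7 * p_lesion] <- legend[["lesion"]]
    labels[right, , k] <- sl
  }
  label_mask(labels, legend = legend, geometry = geometry)
}
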
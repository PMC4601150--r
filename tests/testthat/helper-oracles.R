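# Independent oracles and small fixtures shared across the test files.

# trapezoidal in-band membership, written independently of the package code
oracle_membership <- function(v, lt, ut, ca) {
  if (v <= lt) return(0)
  if (!is.na(ut) && v > ut) return(0)
  if (v >= ca) return(1)
  (v - lt) / (ca - lt)
}

# exhaustive max-min path strengths per seed label by fixed-point iteration
# over the 6-connected grid; label = argmax strength (0 when all zero)
oracle_fc <- function(values, seeds, lt, ut, ca) {
  d <- dim(values)
  g <- array(vapply(values, oracle_membership, numeric(1), lt, ut, ca), dim = d)
  labels_present <- sort(unique(seeds$label))
  strengths <- list()
  for (lb in labels_present) {
    s <- array(0, dim = d)
    for (r in which(seeds$label == lb)) {
      if (g[seeds$i[r], seeds$j[r], seeds$k[r]] > 0)
        s[seeds$i[r], seeds$j[r], seeds$k[r]] <- 1
    }
    repeat {
      s_old <- s
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        if (g[i, j, k] == 0) next
        best <- s[i, j, k]
        for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                        c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
          if (any(nb < 1) || nb[1] > d[1] || nb[2] > d[2] || nb[3] > d[3]) next
          aff <- min(g[i, j, k], g[nb[1], nb[2], nb[3]])
          cand <- min(s[nb[1], nb[2], nb[3]], aff)
          if (cand > best) best <- cand
        }
        s[i, j, k] <- best
      }
      if (identical(s, s_old)) break
    }
    strengths[[as.character(lb)]] <- s
  }
  best <- array(0, dim = d)
  lab <- array(0L, dim = d)
  for (lb in labels_present) {
    s <- strengths[[as.character(lb)]]
    upd <- s > best
    best[upd] <- s[upd]
    lab[upd] <- lb
  }
  list(strength = best, label = lab, per_label = strengths)
}

# AUC by exhaustive pair counting, ties worth one half
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ICC(2,1) from an explicit two-way ANOVA decomposition
oracle_icc21 <- function(X) {
  n <- nrow(X); k <- ncol(X)
  m <- mean(X)
  SSR <- k * sum((rowMeans(X) - m)^2)
  SSC <- n * sum((colMeans(X) - m)^2)
  SST <- sum((X - m)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# rasterized disc image (intensities), centre offset in pixels
disc_image <- function(radius_mm, px_mm, half_mm = radius_mm + 1.5,
                       fg = 300, bg = 50, cx = 0, cy = 0) {
  xs <- seq(-half_mm, half_mm, by = px_mm)
  img <- outer(xs - cx, xs - cy, function(a, b) ifelse(a^2 + b^2 <= radius_mm^2, fg, bg))
  structure(img, step_mm = px_mm, center_px = c((length(xs) + 1) / 2,
                                                (length(xs) + 1) / 2))
}

# compact single-artery phantom (small grid, fast to generate); background 60
# and lumen 300 so LT = 140 exactly on the noise-free scene
tiny_phantom_spec <- function(depth = 0.5, modality = "CTA", noise_sd = 0,
                              seed = 1L, branch = FALSE) {
  sp <- if (modality == "CTA") c(0.5, 0.5, 0.75) else c(0.7, 0.7, 2.0)
  aorta_r <- 6
  z_extent <- 30
  nz <- round(z_extent / sp[3]) + 1
  z_mid <- (nz - 1) / 2 * sp[3]
  y0 <- 0.13
  len <- 24
  path <- rbind(c(aorta_r - 1, y0, z_mid),
                c(aorta_r + len / 2, y0 + 0.8, z_mid),
                c(aorta_r + len, y0 + 1.6, z_mid))
  sten <- data.frame(center_mm = 14, depth = depth, width_mm = 6)
  if (depth == 0) sten <- sten[0, ]
  art <- artery_spec(path, radius_mm = 2.2, stenoses = sten)
  if (branch) {
    child <- artery_spec(rbind(c(aorta_r + 12, y0 + 0.8, z_mid),
                               c(aorta_r + 18, y0 + 7, z_mid),
                               c(aorta_r + 22, y0 + 11, z_mid)),
                         radius_mm = 1.4)
    art <- add_branch(art, child, attach_mm = 13)
  }
  nx <- round((aorta_r + len + 6 + aorta_r + 2) / sp[1]) + 1
  ny <- round(26 / sp[2]) + 1
  spec <- phantom_spec(
    grid_shape = c(nx, ny, nz), voxel_spacing = sp,
    aorta = list(center = c(0, 0), radius_mm = aorta_r, intensity = 300),
    arteries = list(art), background_intensity = 60,
    noise_sd = noise_sd, seed = seed
  )
  attr(spec, "origin") <- c(-aorta_r - 2, -13, 0)
  attr(spec, "junction_mm") <- c(aorta_r, y0 + 1.6 / 25, z_mid)
  spec
}

# cache expensive fixtures across test files (testthat runs them in-process)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_pipeline <- function(depth = 0.5, modality = "CTA") {
  cached(sprintf("pipe_%s_%s", modality, depth), {
    spec <- tiny_phantom_spec(depth = depth, modality = modality)
    cfg <- run_config(modality = modality, seed = 1)
    suppressWarnings(run_pipeline(cfg, phantom = spec))
  })
}

# hand-built segment profile for summarization tests
make_profile <- function(diameter, area = pi * (diameter / 2)^2,
                         eligible = rep(TRUE, length(diameter)),
                         valid = rep(TRUE, length(diameter)),
                         step = 1, segment = 1L) {
  n <- length(diameter)
  out <- tibble::tibble(
    arc_mm = seq(0, by = step, length.out = n),
    dist_aorta_mm = seq(0, by = step, length.out = n),
    x = 0, y = 0, z = 0,
    diameter_mm = diameter, area_mm2 = area,
    valid = valid, max_eligible = eligible & valid
  )
  structure(out, segment = segment, artery = 1L,
            start_bif_mm = NA_real_, end_bif_mm = NA_real_,
            step_mm = step, measurable = any(valid),
            class = c("segment_profile", class(out)))
}
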
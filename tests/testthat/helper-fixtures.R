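# Shared fixtures and independent oracles built in code.

study_tsl <- c(1, 15, 30, 45, 60, 75, 90, 105)

# small two-class phantom carrying per-FSL T1rho truth for recovery tests
recovery_phantom <- function(t1rho_brain = c(`100` = 119, `500` = 100,
                                             `1000` = 98, `2000` = 108),
                             t1rho_tumour = c(`100` = 147, `500` = 127,
                                              `1000` = 126, `2000` = 137),
                             s0 = 100, radius = 1.5) {
  tissue <- list(
    brain = tissue_relaxation(882, 120, t1rho_brain, s0 = s0),
    tumour = tissue_relaxation(988, 139, t1rho_tumour, s0 = s0))
  build_phantom(phantom_spec(tumour_radius_mm = radius, tissue = tissue))
}

# brute-force two-sided Mann-Whitney p by full enumeration of the C(n1+n2, n1)
# rank assignments (no ties), doubling the smaller tail as wilcox.test does
enumerate_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pos <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  us <- apply(pos, 2L, function(ix) sum(ranks[ix])) - n1 * (n1 + 1) / 2
  if (u_obs > n1 * n2 / 2) p <- 2 * mean(us >= u_obs) else
    p <- 2 * mean(us <= u_obs)
  min(p, 1)
}

# literal step-up definition of Benjamini-Hochberg rejection + adjusted p
bh_oracle <- function(p, fdr = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * fdr / m)
  reject_sorted <- rep(FALSE, m)
  if (length(k)) reject_sorted[seq_len(max(k))] <- TRUE
  adj_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  reject <- adjusted <- rep(NA, m)
  reject[o] <- reject_sorted
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = reject)
}

# exhaustive area-overlap label resampling oracle (per slice, direct loops)
resample_oracle <- function(mask, target_grid) {
  src <- mask$grid
  out <- array(0L, c(target_grid$nrow, target_grid$ncol, target_grid$n_slices))
  hs <- src$spacing_mm; ht <- target_grid$spacing_mm
  for (s in seq_len(src$n_slices)) for (i in seq_len(target_grid$nrow))
    for (j in seq_len(target_grid$ncol)) {
      ylo <- (i - 1) * ht[1]; yhi <- i * ht[1]
      xlo <- (j - 1) * ht[2]; xhi <- j * ht[2]
      cov <- c(`1` = 0, `2` = 0)
      for (si in seq_len(src$nrow)) for (sj in seq_len(src$ncol)) {
        lab <- mask$label[si, sj, s]
        if (lab == 0L) next
        oy <- min(yhi, si * hs[1]) - max(ylo, (si - 1) * hs[1])
        ox <- min(xhi, sj * hs[2]) - max(xlo, (sj - 1) * hs[2])
        if (oy > 0 && ox > 0)
          cov[as.character(lab)] <- cov[as.character(lab)] + oy * ox
      }
      cov <- cov / (ht[1] * ht[2])
      hit <- cov >= 0.5 - 1e-12
      if (any(hit)) {
        pick <- names(cov)[hit]
        out[i, j, s] <- max(as.integer(pick))  # tumour wins exact ties
      }
    }
  roi_mask(out, target_grid)
}

# minimal measurement table for statistics-layer tests
toy_measurement_table <- function() {
  rows <- expand.grid(mouse = 1:3, group = 1:3, week = 1:4,
                      fsl_hz = c(100, 500, 1000, 2000))
  rows$fsl_high_hz <- NA_real_
  rows$roi <- "brain"
  rows$metric <- "t1rho"
  set.seed(99)
  rows$value <- 100 + 10 * rows$group + rnorm(nrow(rows), sd = 5)
  as_measurement_table(rows)
}
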
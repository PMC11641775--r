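# Independent oracles and small fixture builders used across tests.

# Naive double-loop chi-square periodogram statistic: explicit column means
# over complete cycles, no vectorization shared with the implementation.
qp_oracle <- function(x, P) {
  K <- length(x) %/% P
  N <- K * P
  y <- x[1:N]
  col_means <- numeric(P)
  for (h in 1:P) {
    s <- 0
    for (k in 0:(K - 1)) s <- s + y[h + k * P]
    col_means[h] <- s / K
  }
  grand <- sum(y) / N
  sh2 <- 0
  for (h in 1:P) sh2 <- sh2 + (col_means[h] - grand)^2
  sh2 <- sh2 / P
  s2 <- 0
  for (i in 1:N) s2 <- s2 + (y[i] - grand)^2
  s2 <- s2 / N
  if (s2 == 0) return(0)
  N * sh2 / s2
}

# Breadth-first connected-component count of a logical mask (4-connectivity),
# independent of EBImage.
flood_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  comps <- list()
  for (j in 1:w) for (i in 1:h) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j))
    seen[i, j] <- TRUE
    px <- integer(0)
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      px <- c(px, (p[2] - 1L) * h + p[1])
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    comps[[length(comps) + 1L]] <- px
  }
  comps
}

# Exhaustive pixel-overlap colocalization oracle: intersect every (pre, post)
# puncta pair pixelwise, pool the overlap pixels, and count connected overlap
# regions of at least min_overlap pixels.
coloc_oracle <- function(pre_labels, post_labels, min_overlap = 1) {
  h <- nrow(pre_labels); w <- ncol(pre_labels)
  overlap <- matrix(FALSE, h, w)
  for (a in setdiff(unique(as.vector(pre_labels)), 0L)) {
    pa <- pre_labels == a
    for (b in setdiff(unique(as.vector(post_labels)), 0L)) {
      overlap <- overlap | (pa & post_labels == b)
    }
  }
  comps <- flood_components(overlap)
  sum(lengths(comps) >= min_overlap)
}

# Random blobby binary mask: union of n random disks.
random_disk_mask <- function(n, size = 64, r_range = c(2, 5)) {
  m <- matrix(FALSE, size, size)
  cx <- runif(n, 4, size - 4)
  cy <- runif(n, 4, size - 4)
  r <- runif(n, r_range[1], r_range[2])
  xs <- matrix(rep(1:size, each = size), size, size)   # column index
  ys <- matrix(rep(1:size, times = size), size, size)  # row index
  for (i in seq_len(n))
    m <- m | ((xs - cx[i])^2 + (ys - cy[i])^2 <= r[i]^2)
  m
}

# Minimal stand-in for a segmented puncta set when only the mask matters.
mask_set <- function(mask) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  comps <- flood_components(mask)
  for (i in seq_along(comps)) labels[comps[[i]]] <- i
  structure(list(mask = mask, labels = labels), class = "puncta_set")
}

# Square-wave record: rest 0, active `rate` during [onset, onset+alpha) per
# 24-h day, 1-min bins, deterministic.
square_wave_record <- function(n_days = 10, onset_h = 12, alpha_h = 12,
                               rate = 10, schedule = light_schedule("DD")) {
  mins <- seq_len(n_days * 1440) - 1
  tod <- (mins / 60) %% 24
  active <- tod >= onset_h & tod < onset_h + alpha_h
  activity_record(ifelse(active, rate, 0), 1, "2024-01-01 08:00:00", schedule)
}

toy_qp_record <- function() {
  # 12 six-hour bins: [10,0,0,0] repeated three times
  activity_record(rep(c(10, 0, 0, 0), 3), 360, "2024-01-01",
                  light_schedule("DD"))
}
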
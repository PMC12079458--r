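# Independent oracles and small fixture builders (everything generated in
# code; no stored data).

# Brute-force reference DBSCAN: O(n^2) distance matrix, textbook expansion.
# Independent of the package's grid-indexed C++ implementation.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1L)) >= min_pts
  lab <- integer(n)
  id <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    id <- id + 1L
    queue <- i
    lab[i] <- id
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      if (!core[p]) next
      for (r in nb[[p]]) {
        if (lab[r] == 0L) {
          lab[r] <- id
          queue <- c(queue, r)
        }
      }
    }
  }
  lab
}

# static localization table from bare coordinates (single frame block)
static_table <- function(x, y, frame = 1L, intensity = 1000,
                         frame_interval = 30) {
  replomics:::as_loc_table(
    data.frame(frame = rep_len(frame, length(x)), x = x, y = y,
               intensity = rep_len(intensity, length(x))),
    frame_interval)
}

# quick small simulated aggregate configs for unit tests (kept light; the
# full-scale runs live in test-acceptance.R)
quick_imaging <- function(seed, n_frames = 120, ...)
  imaging_model(seed = seed, n_frames = n_frames, ...)

expect_partition <- function(seg, n) {
  mem <- unname(unlist(lapply(seg$clusters, `[[`, "members")))
  expect_equal(sort(c(mem, seg$noise)), seq_len(n))
  expect_false(anyDuplicated(mem) > 0)
}
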
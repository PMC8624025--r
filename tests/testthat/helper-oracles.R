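# Independent oracles and fixture builders used across the suite.

# Brute-force flood-fill component labeling (queue-based BFS), the
# independent oracle for segment_hotspots.  Returns 0/positive-integer label
# matrix; label numbering is arbitrary.
flood_fill_label <- function(fg, connectivity = 8L) {
  m <- nrow(fg); n <- ncol(fg)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  lab <- matrix(0L, m, n)
  cur <- 0L
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1L] >= 1 && q[1L] <= m && q[2L] >= 1 && q[2L] <= n &&
            fg[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
          lab[q[1L], q[2L]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Canonical form of a labeling: list of sorted pixel-index sets, sorted by
# first pixel, so two labelings compare independently of label numbering.
canonical_components <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  comps <- lapply(ids, function(k) sort(which(lab == k)))
  comps[order(vapply(comps, `[`, numeric(1), 1L))]
}

random_valid_frame <- function(height = NULL, width = NULL) {
  if (is.null(height)) height <- sample(1:12, 1)
  if (is.null(width)) width <- sample(1:12, 1)
  thermal_frame(matrix(runif(height * width, 28, 40), height, width))
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)
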
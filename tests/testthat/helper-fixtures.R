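# fixture builders and brute-force oracles shared across tests

# write a minimal Phred+33 FASTQ file from integer quality vectors
write_fastq <- function(path, quals, seqs = NULL) {
  lines <- character(0)
  for (i in seq_along(quals)) {
    q <- quals[[i]]
    s <- if (is.null(seqs)) paste(rep("A", length(q)), collapse = "") else seqs[[i]]
    lines <- c(lines, sprintf("@read%d", i), s, "+",
               intToUtf8(q + 33L, multiple = FALSE))
  }
  writeLines(lines, path)
  path
}

# flood-fill connected-component labeling, the oracle for label_components
flood_label <- function(binary, connectivity = 8) {
  b <- binary != 0
  h <- nrow(b); w <- ncol(b)
  lab <- matrix(0L, h, w)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (start in which(b)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      for (k in seq_len(nrow(nbr))) {
        rr <- r + nbr[k, 1]; cc <- c + nbr[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            b[rr, cc] && lab[rr, cc] == 0L) {
          q <- (cc - 1L) * h + rr
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# small non-constant test frame
frame_abcd <- function() matrix(c(1, 3, 2, 4), 2, 2)  # rows: [1 2; 3 4]
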
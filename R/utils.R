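# internal helpers shared across the package

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

# TSV with '.' decimal and LF line endings regardless of locale
write_tsv_raw <- function(df, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, con, sep = "\n")
}

# canonical unordered pair matrix: 2 integer columns, i < j, lexicographic order
canonical_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  p <- matrix(as.integer(pairs), ncol = 2)
  swap <- p[, 1] > p[, 2]
  p[swap, ] <- p[swap, c(2, 1)]
  if (any(p[, 1] == p[, 2])) stop("self pairs are not allowed")
  p <- unique(p)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  dimnames(p) <- list(NULL, c("i", "j"))
  p
}

pair_key <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = "-")

# rotate 3-vector v about unit axis k by angle theta (Rodrigues)
rotate3 <- function(v, k, theta) {
  k <- k / sqrt(sum(k^2))
  v * cos(theta) + cross3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a zero vector")
  v / nv
}

# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
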
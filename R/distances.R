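#' Pairwise distance between two aligned sequences
#'
#' Columns where either sequence carries a gap or an ambiguity symbol are
#' removed (pairwise deletion); over the remaining `n_compared` sites the
#' mismatch proportion `p`, the transition proportion `P` (A<->G, C<->T)
#' and the transversion proportion `Q` (purine<->pyrimidine) are computed,
#' with `p = P + Q`. The model distance is
#'
#' * `p`: `d = p`;
#' * `JC69`: `d = -(3/4) * log(1 - 4p/3)`;
#' * `K80`: `d = -(1/2) * log(1 - 2P - Q) - (1/4) * log(1 - 2Q)`.
#'
#' Saturation (JC69: `p >= 3/4`; K80: a log argument <= 0) yields `d = NA`
#' with `saturated = TRUE` rather than an error.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @param metric One of `"p"`, `"JC69"`, `"K80"`.
#' @return A `distance_result`: list with `p`, `P`, `Q`, `d`, `n_compared`,
#'   `saturated`, `metric`.
#' @examples
#' pair_distance("ACGTACGTAC", "ACGTACGTAC", "JC69")$d # 0
#' @export
pair_distance <- function(a, b, metric = c("p", "JC69", "K80")) {
  metric <- match.arg(metric)
  a <- .norm_seq(a); b <- .norm_seq(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must be aligned to equal lengths", call. = FALSE)
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  keep <- ca %in% bases & cb %in% bases
  n <- sum(keep)
  if (n == 0L) {
    stop("no comparable sites after pairwise deletion", call. = FALSE)
  }
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  purine <- c("A", "G")
  ti <- diff & ((ca %in% purine) == (cb %in% purine))
  P <- sum(ti) / n
  Q <- sum(diff & !ti) / n
  p <- P + Q
  saturated <- FALSE
  d <- switch(metric,
    p = p,
    JC69 = {
      arg <- 1 - 4 * p / 3
      if (arg <= 0) { saturated <- TRUE; NA_real_ }
      else -0.75 * log(arg)
    },
    K80 = {
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      if (a1 <= 0 || a2 <= 0) { saturated <- TRUE; NA_real_ }
      else -0.5 * log(a1) - 0.25 * log(a2)
    }
  )
  structure(list(p = p, P = P, Q = Q, d = d, n_compared = n,
                 saturated = saturated, metric = metric),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> %s: d = %s (p = %.4g, P = %.4g, Q = %.4g, n = %d%s)\n",
              x$metric, format(x$d), x$p, x$P, x$Q, x$n_compared,
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' Pairwise distance matrix of an alignment
#'
#' All pairs via [pair_distance()]; saturated pairs carry `NA` in the
#' matrix and are listed in the `saturated_pairs` attribute.
#'
#' @param aln A nucleotide [alignment()] with at least two sequences.
#' @param metric One of `"p"`, `"JC69"`, `"K80"`.
#' @return A `distance_matrix`: symmetric numeric matrix with zero
#'   diagonal, id dimnames and attributes `metric`, `n_compared` (matrix)
#'   and `saturated_pairs` (2-column id matrix, possibly empty).
#' @export
distance_matrix <- function(aln, metric = c("p", "JC69", "K80")) {
  metric <- match.arg(metric)
  stopifnot(inherits(aln, "alignment"))
  if (aln$alphabet != "nt") stop("distances require a nucleotide alignment",
                                 call. = FALSE)
  n <- length(aln$ids)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  nc <- matrix(NA_integer_, n, n, dimnames = list(aln$ids, aln$ids))
  sat <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- tryCatch(
        pair_distance(aln$seqs[[i]], aln$seqs[[j]], metric),
        error = function(e) {
          stop(sprintf("pair (%s, %s): %s", aln$ids[i], aln$ids[j],
                       conditionMessage(e)), call. = FALSE)
        })
      d[i, j] <- d[j, i] <- r$d
      nc[i, j] <- nc[j, i] <- r$n_compared
      if (r$saturated) sat[[length(sat) + 1L]] <- c(aln$ids[i], aln$ids[j])
    }
  }
  structure(d, metric = metric, n_compared = nc,
            saturated_pairs = do.call(rbind, c(sat, list(matrix(character(), 0, 2)))),
            class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, metric %s, %d saturated pair(s)\n",
              nrow(x), ncol(x), attr(x, "metric"),
              nrow(attr(x, "saturated_pairs"))))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Write / read a distance matrix in square PHYLIP format
#'
#' @param dm A [distance_matrix()] (or plain symmetric matrix with
#'   dimnames).
#' @param path File path.
#' @return `write_phylip_dist` returns `path` invisibly;
#'   `read_phylip_dist` returns a numeric matrix with id dimnames.
#' @export
write_phylip_dist <- function(dm, path) {
  n <- nrow(dm)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste(formatC(rownames(dm)[i], width = -10),
                     paste(sprintf("%.8f", dm[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  ids <- vapply(parts, `[[`, "", 1L)
  m <- do.call(rbind, lapply(parts, function(p) {
    v <- p[-1]
    v[v %in% c("NA", "NaN", "nan")] <- NA_character_
    as.numeric(v)
  }))
  dimnames(m) <- list(ids, ids)
  m
}

#' Long-form export of a distance matrix
#'
#' @param dm A [distance_matrix()].
#' @return Data frame with `id1`, `id2`, `distance`, `n_compared` for each
#'   unordered pair (i < j).
#' @export
dist_long <- function(dm) {
  ids <- rownames(dm)
  n <- length(ids)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  nc <- attr(dm, "n_compared")
  data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
             distance = dm[idx],
             n_compared = if (is.null(nc)) NA_integer_ else nc[idx])
}
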
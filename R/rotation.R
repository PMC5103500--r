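#' Best rotation between two circular sequences
#'
#' Doubles the first sequence and runs FLASM in best-match mode with
#' `text = s_j`: the best tuple `(j, i, e)` identifies the length-`ell`
#' window of the doubled `s_i` most similar to a factor of `s_j`, from
#' which the rotation `r = (i - j) mod length(s_i)` of `s_i` aligns that
#' window with its matching position in `s_j`.
#'
#' @param s_i,s_j circular sequences (linearised strings).
#' @param factor_length comparison window length, at most the shorter
#'   sequence.
#' @param max_distance distance threshold, `< factor_length`.
#' @param model `"hamming"` or `"edit"`.
#' @return A list `(rotation, distance)`, or `NULL` when no window pair is
#'   within `max_distance`.
#' @examples
#' pair_best_rotation("AAGATG", "GATGAA", 6, 0)  # rotation 2, distance 0
#' @export
pair_best_rotation <- function(s_i, s_j, factor_length, max_distance,
                               model = c("hamming", "edit")) {
  model <- match.arg(model)
  s_i <- as_seq(s_i); s_j <- as_seq(s_j)
  m <- nchar(s_i)
  if (factor_length > min(m, nchar(s_j)))
    stop("factor_length exceeds the shorter sequence", call. = FALSE)
  best <- flasm(text = s_j, pattern = double_pattern(s_i),
                factor_length = factor_length, max_distance = max_distance,
                model = model, mode = "best")
  if (nrow(best) == 0L) return(NULL)
  list(rotation = (best$pattern_end[1] - best$text_end[1]) %% m,
       distance = best$distance[1])
}

#' Pairwise rotation/distance matrix for circular sequences
#'
#' Runs [pair_best_rotation()] over every ordered pair of sequences. Pairs
#' with no window within `max_distance` (or shorter than `factor_length`)
#' are recorded with distance `Inf` and rotation 0, and are merged last by
#' [refine_rotations()].
#'
#' @param seqs character vector of N >= 2 sequences.
#' @inheritParams pair_best_rotation
#' @return An object of class `rotation_matrix`: a list with the input
#'   `seqs` and N x N matrices `rotation` and `distance` (diagonal unused:
#'   rotation 0, distance 0).
#' @export
build_rotation_matrix <- function(seqs, factor_length, max_distance,
                                  model = c("hamming", "edit")) {
  model <- match.arg(model)
  seqs <- as_seqs(seqs)
  N <- length(seqs)
  if (N < 2L) stop("at least two sequences are required", call. = FALSE)
  rot <- matrix(0L, N, N, dimnames = list(names(seqs), names(seqs)))
  dst <- matrix(0, N, N, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      if (factor_length > min(nchar(seqs[i]), nchar(seqs[j]))) {
        dst[i, j] <- Inf
        next
      }
      pb <- pair_best_rotation(seqs[i], seqs[j], factor_length, max_distance,
                               model)
      if (is.null(pb)) dst[i, j] <- Inf
      else { rot[i, j] <- pb$rotation; dst[i, j] <- pb$distance }
    }
  }
  structure(list(seqs = seqs, rotation = rot, distance = dst,
                 factor_length = factor_length, max_distance = max_distance,
                 model = model),
            class = "rotation_matrix")
}

#' @export
print.rotation_matrix <- function(x, ...) {
  cat("<rotation_matrix ", length(x$seqs), " sequences, model=", x$model,
      ", ell=", x$factor_length, ", k=", x$max_distance, ">\n", sep = "")
  invisible(x)
}

#' Refine circular sequence rotations
#'
#' Rotates each input sequence so that closely related sequences share an
#' alignment frame, the preprocessing that makes a downstream multiple
#' sequence aligner treat circular inputs sensibly. Sequences are grouped
#' by single-linkage agglomerative clustering on the symmetrised pairwise
#' distance `min(e_ij, e_ji)` from the rotation matrix; at each merge the
#' joining cluster is rotated as a block by the rotation of the
#' minimal-distance cross-pair (rotations compose modulo each sequence's
#' length). The cluster containing the first input sequence always holds
#' the frame, so the first sequence is returned unrotated.
#'
#' @param seqs character vector of N >= 2 sequences.
#' @param matrix a [build_rotation_matrix()] result for `seqs`, or `NULL`
#'   to build one from the remaining arguments.
#' @inheritParams pair_best_rotation
#' @return The rotated sequences (same order and names as the input), with
#'   the applied rotations in `attr(, "rotations")`.
#' @examples
#' s <- c("AAGATGCC", "GATGCCAA", "CCAAGATG")
#' refine_rotations(s, factor_length = 8, max_distance = 0)
#' @export
refine_rotations <- function(seqs, matrix = NULL, factor_length = NULL,
                             max_distance = NULL,
                             model = c("hamming", "edit")) {
  model <- match.arg(model)
  seqs <- as_seqs(seqs)
  N <- length(seqs)
  if (is.null(matrix)) {
    if (is.null(factor_length) || is.null(max_distance))
      stop("either a rotation matrix or factor_length and max_distance are required",
           call. = FALSE)
    matrix <- build_rotation_matrix(seqs, factor_length, max_distance, model)
  }
  stopifnot(inherits(matrix, "rotation_matrix"), length(matrix$seqs) == N)

  sym <- pmin(matrix$distance, t(matrix$distance))
  diag(sym) <- 0
  finite <- sym[is.finite(sym)]
  big <- if (length(finite)) max(finite) + 1 else 1
  sym[!is.finite(sym)] <- big

  lens <- nchar(seqs)
  rho <- integer(N)
  hc <- hclust(as.dist(sym), method = "single")
  cluster_of <- seq_len(N)          # current cluster id per sequence
  for (step in seq_len(nrow(hc$merge))) {
    mm <- hc$merge[step, ]
    members_of <- function(v) {
      if (v < 0L) -v else which(cluster_of == N + v)
    }
    A <- members_of(mm[1]); B <- members_of(mm[2])
    # the cluster holding the smallest original index keeps its frame
    if (min(B) < min(A)) { tmp <- A; A <- B; B <- tmp }
    # minimal-distance cross pair, ties by smallest original indices
    cross <- expand.grid(p = sort(A), q = sort(B))
    dvals <- sym[cbind(cross$p, cross$q)]
    pick <- cross[which.min(dvals), ]        # which.min takes the first tie
    p <- pick$p; q <- pick$q
    # rotation of s_q aligning it to s_p's original frame, then follow p
    r_qp <- matrix$rotation[q, p]
    delta <- (r_qp + rho[p] - rho[q])
    for (b in B) rho[b] <- (rho[b] + delta) %% lens[b]
    cluster_of[c(A, B)] <- N + step
  }
  out <- vapply(seq_len(N), function(i) rotate_string(seqs[i], rho[i]),
                character(1))
  names(out) <- names(seqs)
  attr(out, "rotations") <- rho
  out
}

#' Randomly rotate a set of circular sequences
#'
#' Applies an independent uniform random rotation to each sequence,
#' returning both the rotated sequences and the ground-truth rotations —
#' the fixture for rotation-recovery experiments.
#'
#' @param seqs character vector of sequences.
#' @param seed integer seed; the generator is a pure function of
#'   `(seqs, seed)` and the caller's RNG state is untouched.
#' @return A list with `seqs` (rotated) and `rotations` (the applied
#'   0-based rotation indices).
#' @export
random_rotate <- function(seqs, seed = NULL) {
  seqs <- as_seqs(seqs)
  with_seed(seed, {
    r <- vapply(nchar(seqs), function(m) sample.int(m, 1L) - 1L, integer(1))
    out <- vapply(seq_along(seqs), function(i) rotate_string(seqs[i], r[i]),
                  character(1))
    names(out) <- names(seqs)
    list(seqs = out, rotations = r)
  })
}
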
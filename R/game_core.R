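#' Booleanize expression values against control-group thresholds
#'
#' Codes each expression value as over- or under-expressed relative to the
#' control group of the same gene. Thresholds always come from the control
#' samples (mean `m_c` and standard deviation `sd_c`, sample SD with the
#' `n - 1` denominator), including when the control group itself is
#' booleanized:
#' * `over`:  coded 1 iff `value >= m_c + sd_c`
#' * `under`: coded 1 iff `value <  m_c - sd_c`
#'
#' The asymmetric boundary (`>=` for over, strict `<` for under) is applied
#' literally; for a gene with `sd_c = 0` the rule degenerates to
#' `value >= m_c` (over) / `value < m_c` (under) and the gene is flagged via
#' the `"zero_sd_genes"` attribute.
#'
#' @param expr Log2 expression matrix.
#' @param design Design data.frame.
#' @param direction `"over"` or `"under"`.
#' @param group Which group's columns to return (`"case"` or `"control"`).
#' @return An integer 0/1 matrix restricted to the requested group's columns,
#'   with attributes `direction` and `zero_sd_genes`.
#' @export
booleanize <- function(expr, design, direction = c("over", "under"),
                       group = c("case", "control")) {
  direction <- match.arg(direction)
  group <- match.arg(group)
  B <- booleanize_all(expr, design, direction)
  design <- validate_design(design, expr)
  keep <- design$sample_id[design$group == group]
  structure(B[, keep, drop = FALSE],
            direction = direction,
            zero_sd_genes = attr(B, "zero_sd_genes"))
}

#' @keywords internal
booleanize_all <- function(expr, design, direction) {
  design <- validate_design(design, expr)
  ctrl <- expr[, design$sample_id[design$group == "control"], drop = FALSE]
  m_c <- rowMeans(ctrl)
  sd_c <- sqrt(row_vars(ctrl))
  B <- if (direction == "over") {
    (expr >= m_c + sd_c) * 1L
  } else {
    (expr < m_c - sd_c) * 1L
  }
  storage.mode(B) <- "integer"
  structure(B, direction = direction,
            zero_sd_genes = rownames(expr)[sd_c == 0])
}

#' Construct a microarray game from a boolean matrix
#'
#' The microarray game of a boolean matrix `B` (genes x arrays) is the
#' coalitional game `(N, w)` whose players are the genes and where `w(T)` is
#' the fraction of arrays whose (nonempty) support — the set of genes coded 1
#' in that column — is contained in coalition `T`. Arrays with empty support
#' never count, and `w(empty set) = 0`.
#'
#' @param B Integer 0/1 matrix with gene rownames.
#' @return An object of class `microarray_game`: list with `players`,
#'   `k` (array count), and `supports` (list of integer player indices).
#' @export
microarray_game <- function(B) {
  stopifnot(is.matrix(B), all(B %in% c(0L, 1L)), ncol(B) >= 1L)
  if (is.null(rownames(B))) rownames(B) <- sprintf("g%d", seq_len(nrow(B)))
  supports <- lapply(seq_len(ncol(B)), function(j) which(B[, j] == 1L))
  structure(list(players = rownames(B), k = ncol(B), supports = supports),
            class = "microarray_game")
}

#' Characteristic function of a microarray game
#'
#' @param game A [microarray_game()].
#' @param coalition Character vector of player (gene) names forming `T`.
#' @return `w(T)`, the fraction of arrays whose nonempty support lies
#'   within `T`.
#' @export
characteristic_value <- function(game, coalition) {
  stopifnot(inherits(game, "microarray_game"))
  unknown <- setdiff(coalition, game$players)
  if (length(unknown)) {
    stop("unknown players in coalition: ", paste(unknown, collapse = ", "))
  }
  idx <- match(coalition, game$players)
  member <- logical(length(game$players))
  member[idx] <- TRUE
  hits <- vapply(game$supports, function(s) length(s) > 0 && all(member[s]),
                 logical(1))
  sum(hits) / game$k
}

#' @keywords internal
lcm2 <- function(a, b) a / gcd2(a, b) * b
#' @keywords internal
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Shapley values of a microarray game, closed form
#'
#' Uses the unanimity-game decomposition of the microarray game: each array
#' column with nonempty support `S_j` contributes `1 / (k * |S_j|)` to every
#' gene in `S_j`, so `phi_i = (1/k) * sum over columns containing i of
#' 1/|S_j|`. Runs in `O(n * k)`.
#'
#' With `exact = TRUE` the value is returned as an exact rational:
#' a list with integer `numerator` (per gene) and scalar `denominator`
#' (`k` times the least common multiple of the support sizes), computed in
#' integer arithmetic. Exact mode errors if the denominator would exceed
#' the exact-integer range of a double.
#'
#' @param B Integer 0/1 matrix (genes x arrays).
#' @param exact Return an exact rational representation instead of doubles.
#' @return Named numeric vector of Shapley values (default), or a list
#'   `(numerator, denominator, value)` when `exact = TRUE`.
#' @export
shapley_closed_form <- function(B, exact = FALSE) {
  stopifnot(is.matrix(B), all(B %in% c(0L, 1L)), ncol(B) >= 1L)
  if (is.null(rownames(B))) rownames(B) <- sprintf("g%d", seq_len(nrow(B)))
  k <- ncol(B)
  s <- colSums(B)
  nz <- s > 0
  if (!exact) {
    phi <- if (any(nz)) {
      as.vector(B[, nz, drop = FALSE] %*% (1 / s[nz])) / k
    } else {
      numeric(nrow(B))
    }
    names(phi) <- rownames(B)
    return(phi)
  }
  L <- 1
  for (sz in unique(s[nz])) L <- lcm2(L, sz)
  if (L * k > 2^53) stop("exact representation out of integer-double range")
  num <- if (any(nz)) {
    as.vector(B[, nz, drop = FALSE] %*% (L / s[nz]))
  } else {
    numeric(nrow(B))
  }
  names(num) <- rownames(B)
  list(numerator = num, denominator = L * k, value = num / (L * k))
}

#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Shapley values by exhaustive permutation averaging
#'
#' The defining computation: for every permutation of the player set, each
#' player's marginal contribution `w(P u {i}) - w(P)` over its predecessor
#' set `P` is evaluated directly from the characteristic function, and the
#' values are averaged over all `n!` permutations. Arithmetic is exact:
#' `w * k` is an integer count, so Shapley values are accumulated as integer
#' numerators over `n! * k`. Intended as an independent oracle for
#' [shapley_closed_form()]; refuses `n > 10`.
#'
#' @param B Integer 0/1 matrix (genes x arrays).
#' @param exact Return the exact rational representation.
#' @return Named numeric vector, or `(numerator, denominator, value)` when
#'   `exact = TRUE`.
#' @export
shapley_permutation_oracle <- function(B, exact = FALSE) {
  stopifnot(is.matrix(B), all(B %in% c(0L, 1L)), ncol(B) >= 1L)
  n <- nrow(B)
  if (n > 10L) {
    stop("permutation oracle is factorial in the gene count; ",
         "use shapley_closed_form() for n > 10")
  }
  if (is.null(rownames(B))) rownames(B) <- sprintf("g%d", seq_len(nrow(B)))
  k <- ncol(B)
  supports <- lapply(seq_len(k), function(j) which(B[, j] == 1L))
  nonempty <- supports[lengths(supports) > 0]
  wk <- function(member) {  # w(S) * k, an integer
    sum(vapply(nonempty, function(s) all(member[s]), logical(1)))
  }
  num <- numeric(n)
  perms <- all_permutations(n)
  for (p in perms) {
    member <- logical(n)
    w_prev <- 0L
    for (i in p) {
      member[i] <- TRUE
      w_cur <- wk(member)
      num[i] <- num[i] + (w_cur - w_prev)
      w_prev <- w_cur
    }
  }
  den <- factorial(n) * k
  names(num) <- rownames(B)
  if (exact) list(numerator = num, denominator = den, value = num / den)
  else num / den
}
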
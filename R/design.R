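# Orthogonal-array valuation subsets: the canonical Green and Blue 18-state
# sets, the modulo-3 generator relating them, balance/orthogonality checks,
# and assembly of the 23-state respondent task.

# The two canonical design sets as published in the study's state-mean table.
# Row order within each set is severity order (as printed); sets are compared
# as unordered collections throughout.
.green18 <- c("11123", "12122", "11313", "21212", "13311", "21131",
              "12232", "22213", "22321", "13231", "23322", "32111",
              "23133", "31221", "33112", "31332", "33223", "32333")
.blue18 <- c("13111", "21122", "11223", "12113", "22121", "11331",
             "21312", "13222", "12332", "22231", "31211", "23313",
             "32212", "23233", "31133", "33132", "33321", "32323")

#' Canonical Green design states
#'
#' The 18 design states of the Green valuation subset, taken from a
#' pre-existing 18-row orthogonal array with five 3-level factors
#' (balance: each level six times per dimension; strength 2: every pair of
#' levels across every pair of dimensions exactly twice).
#'
#' @return Character vector of 18 state labels.
#' @export
green_states <- function() .green18

#' Canonical Blue design states
#'
#' The Blue subset is the Green subset shifted by the generator "11111"
#' under modulo-3 level arithmetic (every level cycles 1 -> 2 -> 3 -> 1).
#' The two sets are disjoint.
#'
#' @return Character vector of 18 state labels.
#' @export
blue_states <- function() .blue18

#' Apply a modulo-3 generator to health states
#'
#' Adds a generator state to each state digit-wise under modulo-3 level
#' arithmetic: per dimension the result level is
#' `((level + generator_level - 1) mod 3) + 1`, i.e. the generator's digit
#' is added with 3 wrapping to 1. With the generator "11111" this is the
#' cyclic shift 1 -> 2 -> 3 -> 1, which has order 3 and no fixed points on
#' the 243-state space.
#'
#' @param states character vector of state labels.
#' @param generator a single state label (default `"11111"`).
#' @return Character vector of shifted state labels.
#' @examples
#' apply_generator("11123") # "22231"
#' @export
apply_generator <- function(states, generator = "11111") {
  lev <- state_levels(states)
  gen <- state_levels(parse_state(generator))[1, ]
  shifted <- ((sweep(lev, 2, gen, "+") - 1L) %% 3L) + 1L
  apply(shifted, 1, paste0, collapse = "")
}

#' Check balance and strength-2 orthogonality of a candidate array
#'
#' Counts, for each dimension, how often each level occurs, and for each
#' pair of dimensions, how often each of the nine level combinations occurs.
#' The array is balanced if every level count within a dimension is equal,
#' and of strength 2 if every pairwise combination count is equal.
#'
#' @param states character vector of state labels (the candidate rows).
#' @return An object of class `"oa_check"`: a list with logical flags
#'   `balanced` and `strength2`, the `level_counts` matrix (dimension x
#'   level) and the `pair_counts` array (3 x 3 x dimension-pair), plus
#'   `n_rows` and `distinct`.
#' @examples
#' check_orthogonality(green_states())
#' @export
check_orthogonality <- function(states) {
  if (length(states) == 0) stop("empty state collection", call. = FALSE)
  lev <- state_levels(states)
  level_counts <- sapply(1:3, function(l) colSums(lev == l))
  colnames(level_counts) <- paste0("level", 1:3)
  balanced <- all(apply(level_counts, 1, function(r) length(unique(r)) == 1L))
  pairs <- utils::combn(5, 2)
  pair_counts <- array(0L, dim = c(3, 3, ncol(pairs)),
                       dimnames = list(paste0("l", 1:3), paste0("l", 1:3),
                                       apply(pairs, 2, function(p)
                                         paste(eq5d_dimensions[p], collapse = ":"))))
  for (k in seq_len(ncol(pairs))) {
    tab <- table(factor(lev[, pairs[1, k]], levels = 1:3),
                 factor(lev[, pairs[2, k]], levels = 1:3))
    pair_counts[, , k] <- as.integer(tab)
  }
  strength2 <- length(unique(as.vector(pair_counts))) == 1L
  structure(list(balanced = balanced, strength2 = strength2,
                 level_counts = level_counts, pair_counts = pair_counts,
                 n_rows = length(states),
                 distinct = !anyDuplicated(states)),
            class = "oa_check")
}

#' @export
print.oa_check <- function(x, ...) {
  cat(sprintf("Orthogonal array check: %d rows (%s)\n", x$n_rows,
              if (x$distinct) "all distinct" else "DUPLICATES present"))
  cat(sprintf("  balanced (equal level counts per dimension): %s\n", x$balanced))
  cat(sprintf("  strength 2 (equal pairwise combination counts): %s\n", x$strength2))
  cat("  level counts:\n")
  print(x$level_counts)
  invisible(x)
}

#' Derive a second array by a generator shift
#'
#' Applies [apply_generator()] row-wise and verifies that both the base and
#' the derived arrays satisfy the orthogonal-array invariants (the cyclic
#' level shift preserves balance and strength-2 orthogonality).
#'
#' @param base character vector of state labels forming a valid array.
#' @param generator a single state label.
#' @return Character vector of shifted labels, same length as `base`.
#' @examples
#' setequal(derive_set(green_states()), blue_states()) # TRUE
#' @export
derive_set <- function(base, generator = "11111") {
  chk <- check_orthogonality(base)
  if (!chk$balanced || !chk$strength2) {
    stop("base array fails balance/strength-2 orthogonality", call. = FALSE)
  }
  out <- apply_generator(base, generator)
  chk2 <- check_orthogonality(out)
  stopifnot(chk2$balanced, chk2$strength2)
  out
}

#' Assemble a valuation set from design states, anchors and holdouts
#'
#' A respondent's task set consists of the design states, the three anchors
#' (11111, 33333 and Dead) and up to two holdout states that are valued but
#' excluded from regression. With 18 design states and 2 holdouts the task
#' has 23 states.
#'
#' @param design character vector of design state labels.
#' @param holdouts character vector of 0-2 state labels, not members of
#'   `design`.
#' @param name set name, conventionally `"Green"`, `"Blue"` or a custom
#'   label.
#' @return An object of class `"valuation_set"`: a list with elements
#'   `design`, `anchors`, `holdouts`, `name`.
#' @examples
#' vs <- valuation_set(green_states(), holdouts = c("21111", "33331"),
#'                     name = "Green")
#' length(presented_states(vs)) # 23
#' @export
valuation_set <- function(design, holdouts = character(), name = "custom") {
  design <- parse_state(design)
  if (anyDuplicated(design)) stop("duplicate design states", call. = FALSE)
  if (length(holdouts) > 0) {
    holdouts <- parse_state(holdouts)
    if (length(holdouts) > 2) stop("at most 2 holdout states are supported", call. = FALSE)
    if (anyDuplicated(holdouts)) stop("duplicate holdout states", call. = FALSE)
    overlap <- intersect(holdouts, design)
    if (length(overlap) > 0) {
      stop(sprintf("holdout state(s) %s duplicate design states",
                   paste(overlap, collapse = ", ")), call. = FALSE)
    }
    if (any(holdouts %in% c("11111", "33333"))) {
      stop("anchor states cannot be holdouts", call. = FALSE)
    }
  }
  structure(list(design = design,
                 anchors = c("11111", "33333", dead_token),
                 holdouts = holdouts,
                 name = name),
            class = "valuation_set")
}

#' @export
print.valuation_set <- function(x, ...) {
  cat(sprintf("Valuation set '%s': %d design states + anchors (11111, 33333, Dead)",
              x$name, length(x$design)))
  if (length(x$holdouts)) {
    cat(sprintf(" + %d holdout(s): %s", length(x$holdouts),
                paste(x$holdouts, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' States presented to a respondent
#'
#' @param set a [valuation_set()].
#' @return Character vector: design states, then 11111, 33333, the dead
#'   token, then any holdouts.
#' @export
presented_states <- function(set) {
  stopifnot(inherits(set, "valuation_set"))
  c(set$design, set$anchors, set$holdouts)
}

#' The canonical Green and Blue valuation sets
#'
#' Both sets carry the three anchors; the holdout states used in the
#' original fieldwork are not recoverable from the published record, so the
#' canonical sets ship without holdouts and holdout evaluation requires
#' explicitly supplied labels.
#'
#' @return Named list with elements `Green` and `Blue`, each a
#'   [valuation_set()].
#' @export
canonical_sets <- function() {
  list(Green = valuation_set(.green18, name = "Green"),
       Blue = valuation_set(.blue18, name = "Blue"))
}

#' Code-score profile of a set of states
#'
#' Histogram of code scores (5-15) over the design states, plus the
#' fraction falling in the moderate range 8-11. Orthogonal 18-row subsets
#' concentrate states in that moderate range (more than half), unlike
#' severity-spread subsets.
#'
#' @param x a [valuation_set()] or a character vector of state labels.
#' @return List with `histogram` (named integer vector over scores 5-15),
#'   `fraction_8_11` and `n`.
#' @export
code_score_profile <- function(x) {
  states <- if (inherits(x, "valuation_set")) x$design else parse_state(x)
  cs <- code_score(states)
  hist <- table(factor(cs, levels = 5:15))
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       fraction_8_11 = mean(cs >= 8 & cs <= 11),
       n = length(states))
}
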
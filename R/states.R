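# EQ-5D-3L state space: parsing, code scores, feature encodings, design matrices.
#
# A health state is a 5-digit label over {1,2,3} in the fixed dimension order
# mobility (MO), self-care (SC), usual activities (UA), pain/discomfort (PD),
# anxiety/depression (AD). This digit order is the only one supported.

#' EQ-5D-3L dimension codes
#'
#' Two-letter codes for the five dimensions in label order: mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression.
#'
#' @format Character vector of length 5.
#' @export
eq5d_dimensions <- c("MO", "SC", "UA", "PD", "AD")

#' The reserved token for the dead state
#'
#' "Dead" is not an EQ-5D state and never parses as one; it appears only in
#' respondent records (as an anchor for rescaling). The token is matched
#' case-insensitively in data files and normalised to this value.
#'
#' @format Character scalar, `"DEAD"`.
#' @export
dead_token <- "DEAD"

#' Test for the dead token
#'
#' @param x character vector of state labels.
#' @return Logical vector, `TRUE` where `x` is the dead token (any case).
#' @export
is_dead <- function(x) {
  toupper(trimws(as.character(x))) == dead_token
}

#' Parse and validate EQ-5D-3L state labels
#'
#' Validates that each label has exactly five characters, each a digit in
#' 1-3, and returns the canonical label. The dead token is rejected: it is
#' not a health state.
#'
#' @param x character vector of candidate labels.
#' @return Character vector of validated labels.
#' @examples
#' parse_state("12223")
#' @export
parse_state <- function(x) {
  x <- trimws(as.character(x))
  if (length(x) == 0) stop("no state labels supplied", call. = FALSE)
  bad_len <- nchar(x) != 5L
  if (any(bad_len)) {
    stop(sprintf("invalid state label '%s': expected 5 digits, got %d characters",
                 x[bad_len][1], nchar(x[bad_len][1])), call. = FALSE)
  }
  chars <- strsplit(x, "", fixed = TRUE)
  for (i in seq_along(x)) {
    ok <- chars[[i]] %in% c("1", "2", "3")
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop(sprintf("invalid state label '%s': character '%s' at position %d is not a level in 1-3",
                   x[i], chars[[i]][j], j), call. = FALSE)
    }
  }
  x
}

#' Dimension levels of health states
#'
#' @param states character vector of state labels (validated).
#' @return Integer matrix with one row per state and columns
#'   `MO`, `SC`, `UA`, `PD`, `AD`.
#' @export
state_levels <- function(states) {
  states <- parse_state(states)
  m <- matrix(as.integer(unlist(strsplit(states, "", fixed = TRUE))),
              ncol = 5L, byrow = TRUE,
              dimnames = list(states, eq5d_dimensions))
  m
}

#' Code score of health states
#'
#' The code score is the sum of the five dimension levels, a crude severity
#' index ranging from 5 (state 11111) to 15 (state 33333).
#'
#' @param states character vector of state labels.
#' @return Integer vector of code scores.
#' @examples
#' code_score(c("11111", "12223", "33333")) # 5, 10, 15
#' @export
code_score <- function(states) {
  as.integer(rowSums(state_levels(states)))
}

#' Enumerate the full EQ-5D-3L state space
#'
#' @return Character vector of all 243 state labels in lexicographic order,
#'   from "11111" to "33333".
#' @export
all_states <- function() {
  g <- expand.grid(AD = 1:3, PD = 1:3, UA = 1:3, SC = 1:3, MO = 1:3)
  sort(paste0(g$MO, g$SC, g$UA, g$PD, g$AD))
}

# names of the ten reference-coded dimension dummies (level 1 = reference)
dummy_names <- function() {
  as.vector(t(outer(eq5d_dimensions, 2:3, paste0)))
}

#' Supported extra regression terms
#'
#' `N1`, `N2`, `N3` indicate the presence of any level-1/2/3 response in a
#' state; `C1`, `C2`, `C3` count the level-1/2/3 digits (summing to 5);
#' `C1Sq`, `C2Sq`, `C3Sq` are the squared counts. Note that `C1`, `C2` and
#' `C3` are exact linear combinations of the ten dimension dummies plus a
#' constant, so models including them alongside the dummies are
#' rank-deficient by construction.
#'
#' @format Character vector, including `"none"`.
#' @export
extra_terms <- c("none", "N1", "N2", "N3", "C1", "C2", "C3",
                 "C1Sq", "C2Sq", "C3Sq")

#' Feature encodings of health states
#'
#' Computes, for each state, the ten reference-coded dimension dummies
#' (`MO2`, `MO3`, ..., `AD3`; level 1 is the reference so state 11111 is the
#' all-zero row), the presence indicators `N1`/`N2`/`N3`, the level counts
#' `C1`/`C2`/`C3` and their squares, and the code score.
#'
#' @param states character vector of state labels.
#' @return Data frame with one row per state, a `state` column and the
#'   feature columns described above.
#' @examples
#' state_features("21312")
#' @export
state_features <- function(states) {
  lev <- state_levels(states)
  out <- data.frame(state = rownames(lev), stringsAsFactors = FALSE)
  for (d in seq_along(eq5d_dimensions)) {
    for (l in 2:3) {
      out[[paste0(eq5d_dimensions[d], l)]] <- as.integer(lev[, d] == l)
    }
  }
  for (l in 1:3) out[[paste0("N", l)]] <- as.integer(rowSums(lev == l) > 0)
  for (l in 1:3) out[[paste0("C", l)]] <- as.integer(rowSums(lev == l))
  for (l in 1:3) out[[paste0("C", l, "Sq")]] <- out[[paste0("C", l)]]^2
  out$code_score <- as.integer(rowSums(lev))
  rownames(out) <- NULL
  out
}

#' Regression design matrix for health states
#'
#' Builds the regressor matrix used by the utility models: the ten dimension
#' dummies, optionally one extra term, and optionally a unit column. Column
#' order is fixed as `MO2, MO3, SC2, SC3, UA2, UA3, PD2, PD3, AD2, AD3`,
#' then the extra term, then `Constant`.
#'
#' @param states character vector of state labels.
#' @param extra one of [extra_terms]; `"none"` adds no extra column.
#' @param constant logical; append a unit column named `Constant`?
#' @return Numeric matrix with rownames equal to the state labels.
#' @examples
#' design_matrix(c("11111", "33333"), extra = "N3")
#' @export
design_matrix <- function(states, extra = "none", constant = TRUE) {
  if (length(extra) != 1L || !extra %in% extra_terms) {
    stop(sprintf("unknown extra term '%s'; must be one of: %s",
                 paste(extra, collapse = ","), paste(extra_terms, collapse = ", ")),
         call. = FALSE)
  }
  feats <- state_features(states)
  cols <- dummy_names()
  if (extra != "none") cols <- c(cols, extra)
  X <- as.matrix(feats[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (isTRUE(constant)) X <- cbind(X, Constant = 1)
  rownames(X) <- feats$state
  X
}
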
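#' @useDynLib shellphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical cell encoding
#
# A cell of a character matrix is stored as a plain string:
#   "?"      missing
#   "-"      inapplicable
#   "0"      a single observed state
#   "0/2"    a polymorphic observation (set of states, ascending, "/"-joined)
# State labels are non-negative integers; on disk they are written with the
# symbol alphabet below (state 10 = "A", ...). Keeping cells as strings makes
# matrices human-readable and makes write->read round trips trivially exact.

.SYMBOLS <- c(0:9, LETTERS, letters)  # state s is written .SYMBOLS[s + 1]

.state_to_symbol <- function(s) {
  if (any(s >= length(.SYMBOLS)))
    stop("unsupported symbol: state label ", max(s), " is too large")
  as.character(.SYMBOLS[s + 1L])
}

.symbol_to_state <- function(ch, symbols = NULL) {
  if (!is.null(symbols)) {
    idx <- match(ch, symbols)
  } else {
    idx <- match(ch, as.character(.SYMBOLS))
  }
  idx - 1L
}

#' Build a canonical cell string from a set of states
#'
#' @param states integer vector of observed state labels (may be empty).
#' @return a canonical cell string; an empty set yields the missing cell `"?"`.
#' @examples
#' cell_from_states(c(1, 0))  # "0/1"
#' @export
cell_from_states <- function(states) {
  states <- unique(as.integer(states))
  if (length(states) == 0) return("?")
  if (any(states < 0)) stop("state labels must be non-negative")
  paste(sort(states), collapse = "/")
}

#' Decode a cell string into its state set
#'
#' @param cell a cell string (`"?"`, `"-"`, `"0"`, `"0/1"`, ...).
#' @return integer vector of states, or `NULL` for missing/inapplicable cells.
#' @export
cell_states <- function(cell) {
  if (is.na(cell) || cell == "?" || cell == "-") return(NULL)
  as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
}

#' @rdname cell_states
#' @export
cell_is_missing <- function(cell) is.na(cell) | cell == "?"

#' @rdname cell_states
#' @export
cell_is_inapplicable <- function(cell) !is.na(cell) & cell == "-"

#' @rdname cell_states
#' @export
cell_is_observed <- function(cell) !cell_is_missing(cell) & !cell_is_inapplicable(cell)

#' @rdname cell_states
#' @export
cell_is_polymorphic <- function(cell) {
  cell_is_observed(cell) & grepl("/", cell, fixed = TRUE)
}

# state list for a vector of cells; NULL elements for ?/-
cells_state_list <- function(cells) {
  lapply(cells, cell_states)
}

#' Scalarize a cell for rank statistics
#'
#' Polymorphic observations enter rank-based statistics as the arithmetic mean
#' of their states (e.g., `"0/1"` -> 0.5); missing and inapplicable cells map
#' to `NA`.
#'
#' @param cells character vector of cell strings.
#' @return numeric vector.
#' @export
cell_scalar <- function(cells) {
  vapply(cells, function(cc) {
    st <- cell_states(cc)
    if (is.null(st)) NA_real_ else mean(st)
  }, numeric(1), USE.NAMES = FALSE)
}

# Render one cell for a given output dialect.
format_cell <- function(cell, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (cell_is_missing(cell)) return("?")
  if (cell_is_inapplicable(cell)) return("-")
  st <- cell_states(cell)
  sym <- paste(.state_to_symbol(st), collapse = "")
  if (length(st) == 1) return(sym)
  if (dialect == "tnt") paste0("[", sym, "]") else paste0("{", sym, "}")
}

# Bitmask of a cell given the character's state count; missing/inapplicable
# get the full set (uncertainty semantics used throughout the engine).
cell_bitmask <- function(cell, n_states) {
  if (!cell_is_observed(cell)) return(bitwShiftL(1L, n_states) - 1L)
  st <- cell_states(cell)
  if (any(st >= n_states))
    stop("state label ", max(st), " out of range for a character with ",
         n_states, " states")
  sum(bitwShiftL(1L, st))
}
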
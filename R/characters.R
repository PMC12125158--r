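# Character metadata ----------------------------------------------------------

#' Construct and validate a character-definition table
#'
#' A character definition table has one row per matrix column and carries the
#' metadata the coding and analysis stages need: the size of the state space,
#' whether the states form an ordered morphocline, whether expression of the
#' character tracks skeletal maturity (so species must be coded from their most
#' mature individuals), measurement bin edges and polymorphism margins for
#' morphometric characters, and an `active` flag (helper observation columns
#' are carried in the matrix but deactivated for analysis).
#'
#' @param index 1-based character numbers.
#' @param name free-text character names.
#' @param n_states number of states (>= 2); state labels are `0:(n_states-1)`.
#' @param ordered logical; ordered (additive) characters are scored with
#'   linear |i - j| step costs.
#' @param ontogeny_controlled logical; see [code_ontogenetic()].
#' @param active logical; inactive columns are excluded from analysis output.
#' @param bin_edges character; ascending thresholds `";"`-joined (e.g.
#'   `"30;50;70"`), or `""`/`NA` for qualitative characters.
#' @param margin numeric; half-width of the polymorphic band around each bin
#'   edge, in the same units as the edges (`NA` if none).
#' @param unit measurement unit label (informational).
#' @param alt_bin_edges optional alternative (coarser) binning, same format.
#' @return a `data.frame` of class `character_defs`.
#' @export
character_defs <- function(index, name = paste0("char", index), n_states = 2L,
                           ordered = FALSE, ontogeny_controlled = FALSE,
                           active = TRUE, bin_edges = NA_character_,
                           margin = NA_real_, unit = NA_character_,
                           alt_bin_edges = NA_character_) {
  n <- length(index)
  df <- data.frame(
    index = as.integer(index),
    name = rep_len(as.character(name), n),
    n_states = rep_len(as.integer(n_states), n),
    ordered = rep_len(as.logical(ordered), n),
    ontogeny_controlled = rep_len(as.logical(ontogeny_controlled), n),
    active = rep_len(as.logical(active), n),
    bin_edges = rep_len(as.character(bin_edges), n),
    margin = rep_len(as.numeric(margin), n),
    unit = rep_len(as.character(unit), n),
    alt_bin_edges = rep_len(as.character(alt_bin_edges), n),
    stringsAsFactors = FALSE
  )
  validate_character_defs(df)
}

validate_character_defs <- function(df) {
  stopifnot(is.data.frame(df), all(c("index", "n_states", "ordered") %in% names(df)))
  if (anyDuplicated(df$index)) stop("duplicated character indices")
  if (any(df$n_states < 2)) stop("characters need at least 2 states")
  for (i in seq_len(nrow(df))) {
    ed <- parse_bin_edges(df$bin_edges[i])
    if (!is.null(ed)) {
      if (is.unsorted(ed, strictly = TRUE))
        stop("bin_edges of character ", df$index[i], " must be strictly ascending")
      mg <- df$margin[i]
      if (!is.na(mg)) {
        if (mg < 0) stop("margin must be non-negative")
        if (length(ed) > 1 && mg >= min(diff(ed)) / 2)
          stop("margin of character ", df$index[i],
               " must be smaller than half the smallest bin width")
      }
    }
  }
  class(df) <- c("character_defs", "data.frame")
  df
}

parse_bin_edges <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Shipped metadata for the 69 trionychid shell characters
#'
#' Returns the character-definition table distributed with the package:
#' the 69 shell characters plus the deactivated helper column from which the
#' two suprascapular-fontanelle characters are derived. The 36 morphocline
#' characters (1, 3, 5, 6, 8, 10, 11, 17, 18, 21, 22, 24, 26, 31, 34, 35, 39,
#' 41-44, 47, 48, 51-54, 56, 58-62, 65, 66, 68) are flagged `ordered`;
#' maturity-coded characters are flagged `ontogeny_controlled`; measurement
#' bin edges and polymorphism margins are filled in where the character is
#' defined by thresholds (e.g., nuchal-callosity width with edges 30/50/70%
#' and a 3-percentage-point margin).
#'
#' @return a `character_defs` data.frame with 70 rows.
#' @export
trionychid_characters <- function() {
  path <- system.file("extdata", "trionychid_characters.csv",
                      package = "shellphylo", mustWork = TRUE)
  read_character_defs(path)
}

#' Read / write a character-metadata sidecar file
#'
#' The sidecar is a plain CSV mirror of [character_defs()].
#'
#' @param path file path.
#' @param defs a `character_defs` table.
#' @return `read_character_defs()` returns a `character_defs` table;
#'   `write_character_defs()` returns `path` invisibly.
#' @export
read_character_defs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bin_edges = "character",
                                       alt_bin_edges = "character"))
  df$bin_edges[!nzchar(df$bin_edges)] <- NA_character_
  df$alt_bin_edges[!nzchar(df$alt_bin_edges)] <- NA_character_
  validate_character_defs(df)
}

#' @rdname read_character_defs
#' @export
write_character_defs <- function(defs, path) {
  utils::write.csv(defs, path, row.names = FALSE, na = "")
  invisible(path)
}
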
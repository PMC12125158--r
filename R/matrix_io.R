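# Individual-level and species-level matrix containers and NEXUS/TNT I/O.
#
# The NEXUS reader is written here rather than delegated: polymorphic cells in
# the deposited matrices appear in four dialects -- {01}, (01), 0/1 and 0\1 --
# and no installed reader normalizes all of them. All four are canonicalized
# to the package's "/"-joined set representation at parse time.

# specimen_set -----------------------------------------------------------------

#' Construct a specimen set (individual-level matrix)
#'
#' @param cells character matrix (specimens x characters) of canonical cell
#'   strings (see [cell_from_states()]).
#' @param meta data.frame with one row per specimen: `specimen_id`,
#'   `species_id`, optional `carapace_length_cm`, `relative_maturity_pct`,
#'   `comments`.
#' @param chars a [character_defs()] table with one row per matrix column.
#' @param abnormal optional logical matrix (same shape as `cells`) flagging
#'   cells scored on abnormal morphology; abnormal observations can be
#'   excluded from species coding.
#' @return an object of class `specimen_set`.
#' @export
specimen_set <- function(cells, meta, chars, abnormal = NULL) {
  cells <- as.matrix(cells)
  stopifnot(nrow(cells) == nrow(meta), ncol(cells) == nrow(chars))
  if (is.null(abnormal))
    abnormal <- matrix(FALSE, nrow(cells), ncol(cells))
  stopifnot(identical(dim(abnormal), dim(cells)))
  if (!"specimen_id" %in% names(meta)) stop("meta needs a specimen_id column")
  if (!"species_id" %in% names(meta)) stop("meta needs a species_id column")
  for (col in c("carapace_length_cm", "relative_maturity_pct"))
    if (!col %in% names(meta)) meta[[col]] <- NA_real_
  if (!"comments" %in% names(meta)) meta$comments <- ""
  rownames(cells) <- meta$specimen_id
  structure(list(cells = cells, meta = meta,
                 chars = validate_character_defs(chars), abnormal = abnormal),
            class = "specimen_set")
}

#' @export
print.specimen_set <- function(x, ...) {
  cat("specimen_set:", nrow(x$cells), "specimens,",
      length(unique(x$meta$species_id)), "species,",
      ncol(x$cells), "characters\n")
  invisible(x)
}

# coded_matrix ------------------------------------------------------------------

#' Construct a species-level coded matrix
#'
#' @param taxa character vector of species ids (row order).
#' @param chars a [character_defs()] table.
#' @param cells character matrix (taxa x characters) of canonical cell strings.
#' @param variant `"minpoly"` (polymorphism reduced by the frequency filter and
#'   maturity rule) or `"maxpoly"` (all observed polymorphism retained).
#' @return an object of class `coded_matrix`.
#' @export
coded_matrix <- function(taxa, chars, cells, variant = c("minpoly", "maxpoly")) {
  variant <- match.arg(variant)
  cells <- as.matrix(cells)
  stopifnot(nrow(cells) == length(taxa), ncol(cells) == nrow(chars))
  rownames(cells) <- taxa
  structure(list(taxa = as.character(taxa),
                 chars = validate_character_defs(chars),
                 cells = cells, variant = variant),
            class = "coded_matrix")
}

#' @export
print.coded_matrix <- function(x, ...) {
  cat("coded_matrix (", x$variant, "): ", length(x$taxa), " taxa x ",
      sum(x$chars$active), " active characters (", nrow(x$chars),
      " total)\n", sep = "")
  invisible(x)
}

# Parsing -----------------------------------------------------------------------

# Tokenize one row of matrix symbols into canonical cells. Returns
# list(cells=..., comments=...). `origin` is used in error messages.
parse_symbol_row <- function(text, symbols, missing_char = "?",
                             gap_char = "-", origin = "row") {
  chars_vec <- strsplit(text, "")[[1]]
  cells <- character(0)
  comments <- character(0)
  i <- 1L
  n <- length(chars_vec)
  to_state <- function(ch, col) {
    st <- .symbol_to_state(ch, symbols)
    if (is.na(st))
      stop("unknown symbol '", ch, "' in ", origin, ", character ", col)
    st
  }
  while (i <= n) {
    ch <- chars_vec[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    col <- length(cells) + 1L
    if (ch == "[") {
      j <- i
      while (j <= n && chars_vec[j] != "]") j <- j + 1L
      comments <- c(comments, paste(chars_vec[(i + 1):(j - 1)], collapse = ""))
      i <- j + 1L
    } else if (ch == missing_char) {
      cells <- c(cells, "?"); i <- i + 1L
    } else if (ch == gap_char) {
      cells <- c(cells, "-"); i <- i + 1L
    } else if (ch == "{" || ch == "(") {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      states <- integer(0)
      while (j <= n && chars_vec[j] != close) {
        if (!grepl("^\\s$", chars_vec[j]))
          states <- c(states, to_state(chars_vec[j], col))
        j <- j + 1L
      }
      if (j > n) stop("unclosed '", ch, "' in ", origin)
      cells <- c(cells, cell_from_states(states))
      i <- j + 1L
    } else {
      states <- to_state(ch, col)
      i <- i + 1L
      # slash / backslash polymorphism chains: 0/1, 0\1, 0/1/2 ...
      while (i < n && (chars_vec[i] == "/" || chars_vec[i] == "\\")) {
        states <- c(states, to_state(chars_vec[i + 1L], col))
        i <- i + 2L
      }
      cells <- c(cells, cell_from_states(states))
    }
  }
  list(cells = cells, comments = comments)
}

# Pull `KEY=value` (value possibly quoted) out of a NEXUS command line.
nexus_field <- function(line, key) {
  m <- regmatches(line, regexpr(paste0("(?i)", key, "\\s*=\\s*(\"[^\"]*\"|'[^']*'|\\S+)"),
                                line, perl = TRUE))
  if (length(m) == 0) return(NULL)
  val <- sub(paste0("(?i)", key, "\\s*=\\s*"), "", m, perl = TRUE)
  gsub("^['\"]|['\"]$", "", gsub(";$", "", val))
}

# Split a matrix row into (label, rest); labels may be quoted with spaces.
split_label <- function(line) {
  line <- sub("^\\s+", "", line)
  if (startsWith(line, "'")) {
    close <- regexpr("'", substring(line, 2), fixed = TRUE)
    if (close < 0) stop("unterminated quoted taxon label")
    label <- substr(line, 2, close)
    rest <- substring(line, close + 2)
  } else {
    sp <- regexpr("\\s", line)
    if (sp < 0) { label <- line; rest <- "" }
    else { label <- substr(line, 1, sp - 1); rest <- substring(line, sp + 1) }
  }
  list(label = label, rest = rest)
}

# Core NEXUS CHARACTERS/DATA-block parser shared by the individual-level and
# species-level readers.
parse_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file: ", path)
  ntax <- as.integer(nexus_field(txt, "NTAX"))
  nchar_ <- as.integer(nexus_field(txt, "NCHAR"))
  if (is.na(ntax) || is.na(nchar_))
    stop("DIMENSIONS line with NTAX and NCHAR is required")
  symbols_str <- nexus_field(txt, "SYMBOLS")
  symbols <- if (is.null(symbols_str)) as.character(.SYMBOLS)
             else strsplit(gsub("\\s", "", symbols_str), "")[[1]]
  missing_char <- nexus_field(txt, "MISSING"); if (is.null(missing_char)) missing_char <- "?"
  gap_char <- nexus_field(txt, "GAP"); if (is.null(gap_char)) gap_char <- "-"

  mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (length(mstart) == 0) stop("no MATRIX command found")
  mstart <- mstart[1]
  body <- lines[(mstart + 1):length(lines)]
  mend <- grep("^\\s*;\\s*$", body)[1]
  if (is.na(mend)) stop("MATRIX block not terminated by ';'")
  body <- body[seq_len(mend - 1)]
  body <- body[nzchar(trimws(body))]

  labels <- character(0); cells <- list(); comments <- character(0)
  i <- 1L
  while (i <= length(body)) {
    parts <- split_label(body[i])
    parsed <- parse_symbol_row(parts$rest, symbols, missing_char, gap_char,
                               origin = paste0("row '", parts$label, "'"))
    row_cells <- parsed$cells
    row_comments <- parsed$comments
    i <- i + 1L
    # wrapped rows: keep consuming lines until the expected column count
    while (length(row_cells) < nchar_ && i <= length(body) &&
           !grepl("\\S\\s", body[i])) {
      more <- parse_symbol_row(body[i], symbols, missing_char, gap_char,
                               origin = paste0("row '", parts$label, "'"))
      row_cells <- c(row_cells, more$cells)
      row_comments <- c(row_comments, more$comments)
      i <- i + 1L
    }
    if (length(row_cells) != nchar_)
      stop("row '", parts$label, "' has ", length(row_cells),
           " characters, expected ", nchar_, " (ragged matrix)")
    labels <- c(labels, parts$label)
    cells[[length(cells) + 1L]] <- row_cells
    comments <- c(comments, paste(row_comments, collapse = " | "))
  }
  if (length(labels) != ntax)
    stop("parsed ", length(labels), " rows but DIMENSIONS declares NTAX=", ntax)
  mat <- do.call(rbind, cells)
  # ordered-set declaration, if present (TYPESET ... ord: 1 3 5 ...)
  ord_idx <- integer(0)
  tm <- regmatches(txt, regexpr("(?is)TYPESET[^;]*;", txt, perl = TRUE))
  if (length(tm) == 1) {
    om <- regmatches(tm, regexpr("(?i)ord\\s*:[^,;]*", tm, perl = TRUE))
    if (length(om) == 1)
      ord_idx <- as.integer(strsplit(trimws(sub("(?i)ord\\s*:", "", om, perl = TRUE)),
                                     "\\s+")[[1]])
  }
  list(labels = labels, cells = mat, comments = comments, ordered = ord_idx)
}

#' Read an individual-level NEXUS matrix
#'
#' Each matrix row is one specimen. Polymorphism may be written in any of the
#' four dialects `{01}`, `(01)`, `0/1` or `0\1`; all are normalized to the
#' canonical set representation. `?` becomes missing and `-` inapplicable.
#' Square-bracket comments inside a row are preserved verbatim on that
#' specimen. By default the species assignment is derived from the row label
#' using the `species__specimen` double-underscore convention (the label is
#' used as both if no separator is present); a metadata sidecar
#' ([read_specimen_metadata()]) can override it.
#'
#' @param path NEXUS file path.
#' @param chars optional [character_defs()]; defaults to unordered binary-or-
#'   larger defaults inferred from the data (state space = max observed + 1,
#'   minimum 2).
#' @return a [specimen_set()].
#' @export
read_individual_nexus <- function(path, chars = NULL) {
  parsed <- parse_nexus_matrix(path)
  nchar_ <- ncol(parsed$cells)
  if (is.null(chars)) {
    nst <- apply(parsed$cells, 2, function(col) {
      mx <- suppressWarnings(max(c(-1L, unlist(cells_state_list(col)))))
      max(2L, mx + 1L)
    })
    chars <- character_defs(seq_len(nchar_), n_states = nst)
    if (length(parsed$ordered)) chars$ordered[parsed$ordered] <- TRUE
  }
  if (nrow(chars) != nchar_)
    stop("metadata has ", nrow(chars), " characters but matrix has ", nchar_)
  # validate every state label against the declared state space
  for (j in seq_len(nchar_)) {
    sts <- unlist(cells_state_list(parsed$cells[, j]))
    if (length(sts) && max(sts) >= chars$n_states[j])
      stop("state ", max(sts), " of character ", chars$index[j],
           " exceeds its declared state space")
  }
  has_sep <- grepl("__", parsed$labels, fixed = TRUE)
  species <- ifelse(has_sep, sub("__.*$", "", parsed$labels), parsed$labels)
  specimen <- ifelse(has_sep, sub("^.*?__", "", parsed$labels), parsed$labels)
  meta <- data.frame(specimen_id = specimen, species_id = species,
                     comments = parsed$comments, stringsAsFactors = FALSE)
  specimen_set(parsed$cells, meta, chars)
}

#' Attach a specimen metadata sidecar
#'
#' Reads a CSV with columns `specimen_id` and any of `species_id`,
#' `carapace_length_cm`, `relative_maturity_pct`, plus optional
#' `abnormal_characters` (a `";"`-joined list of character indices whose
#' scoring in that specimen reflects abnormal morphology), and merges it into
#' a [specimen_set()].
#'
#' @param specimens a `specimen_set`.
#' @param path sidecar CSV path.
#' @return the updated `specimen_set`.
#' @export
read_specimen_metadata <- function(specimens, path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("specimen_id" %in% names(sc))
  idx <- match(specimens$meta$specimen_id, sc$specimen_id)
  for (col in c("species_id", "carapace_length_cm", "relative_maturity_pct")) {
    if (col %in% names(sc)) {
      ok <- !is.na(idx)
      specimens$meta[[col]][ok] <- sc[[col]][idx[ok]]
    }
  }
  if ("abnormal_characters" %in% names(sc)) {
    for (i in which(!is.na(idx))) {
      spec <- sc$abnormal_characters[idx[i]]
      if (!is.na(spec) && nzchar(spec)) {
        cols <- as.integer(strsplit(spec, ";", fixed = TRUE)[[1]])
        specimens$abnormal[i, cols] <- TRUE
      }
    }
  }
  specimens
}

# Writing -----------------------------------------------------------------------

quote_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.]", x), paste0("'", x, "'"), x)
}

#' Write a species-level matrix (NEXUS or TNT)
#'
#' The NEXUS dialect round-trips through [read_species_nexus()]; the ordered
#' character set is emitted as an `ASSUMPTIONS`/`TYPESET` block (NEXUS) or a
#' `ccode` line (TNT). Inactive helper columns are excluded by default.
#'
#' @param matrix_ a [coded_matrix()].
#' @param path output file.
#' @param dialect `"nexus"` or `"tnt"`.
#' @param include_inactive keep deactivated columns in the output?
#' @return `path`, invisibly.
#' @export
write_species_matrix <- function(matrix_, path, dialect = c("nexus", "tnt"),
                                 include_inactive = FALSE) {
  dialect <- match.arg(dialect)
  keep <- if (include_inactive) seq_len(nrow(matrix_$chars)) else
    which(matrix_$chars$active)
  chars <- matrix_$chars[keep, , drop = FALSE]
  cells <- matrix_$cells[, keep, drop = FALSE]
  if (any(chars$n_states > 32))
    stop("unsupported symbol: characters with more than 32 states cannot be written")
  body <- vapply(seq_along(matrix_$taxa), function(i) {
    paste0(format(quote_label(matrix_$taxa[i]), width = 34), " ",
           paste(vapply(cells[i, ], format_cell, "", dialect = dialect),
                 collapse = ""))
  }, "")
  ord <- which(chars$ordered)
  if (dialect == "nexus") {
    nsym <- max(chars$n_states)
    out <- c("#NEXUS",
             paste0("[", matrix_$variant, " species-level matrix written by shellphylo]"),
             "BEGIN DATA;",
             paste0("DIMENSIONS NTAX=", length(matrix_$taxa),
                    " NCHAR=", ncol(cells), ";"),
             paste0("FORMAT DATATYPE=STANDARD SYMBOLS=\"",
                    paste(.state_to_symbol(0:(nsym - 1)), collapse = ""),
                    "\" MISSING=? GAP=-;"),
             "MATRIX", body, ";", "END;")
    if (length(ord)) {
      unord <- setdiff(seq_len(ncol(cells)), ord)
      ts <- paste0("TYPESET * default = ord: ", paste(ord, collapse = " "),
                   if (length(unord)) paste0(", unord: ",
                                             paste(unord, collapse = " ")),
                   ";")
      out <- c(out, "BEGIN ASSUMPTIONS;", ts, "END;")
    }
  } else {
    out <- c("xread",
             paste0("'", matrix_$variant, " matrix written by shellphylo'"),
             paste(ncol(cells), length(matrix_$taxa)),
             body, ";")
    if (length(ord))
      out <- c(out, paste0("ccode + ", paste(ord - 1L, collapse = " "), ";"))
    out <- c(out, "proc /;")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a species-level NEXUS matrix
#'
#' @param path NEXUS file written by [write_species_matrix()] (or compatible).
#' @param chars optional [character_defs()] (inferred if omitted; a `TYPESET`
#'   block restores the ordered set).
#' @param variant recorded matrix variant.
#' @return a [coded_matrix()].
#' @export
read_species_nexus <- function(path, chars = NULL,
                               variant = c("minpoly", "maxpoly")) {
  variant <- match.arg(variant)
  parsed <- parse_nexus_matrix(path)
  if (is.null(chars)) {
    nst <- apply(parsed$cells, 2, function(col) {
      mx <- suppressWarnings(max(c(-1L, unlist(cells_state_list(col)))))
      max(2L, mx + 1L)
    })
    chars <- character_defs(seq_len(ncol(parsed$cells)), n_states = nst)
    if (length(parsed$ordered)) chars$ordered[parsed$ordered] <- TRUE
  }
  coded_matrix(parsed$labels, chars, parsed$cells, variant)
}

#' Write an individual-level NEXUS matrix
#'
#' Row labels use the `species__specimen` convention understood by
#' [read_individual_nexus()].
#'
#' @param specimens a [specimen_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_individual_nexus <- function(specimens, path) {
  labels <- paste0(specimens$meta$species_id, "__", specimens$meta$specimen_id)
  nsym <- max(specimens$chars$n_states)
  body <- vapply(seq_len(nrow(specimens$cells)), function(i) {
    paste0(format(quote_label(labels[i]), width = 44), " ",
           paste(vapply(specimens$cells[i, ], format_cell, "",
                        dialect = "nexus"), collapse = ""))
  }, "")
  ord <- which(specimens$chars$ordered)
  out <- c("#NEXUS",
           "[individual-level matrix written by shellphylo]",
           "BEGIN DATA;",
           paste0("DIMENSIONS NTAX=", nrow(specimens$cells),
                  " NCHAR=", ncol(specimens$cells), ";"),
           paste0("FORMAT DATATYPE=STANDARD SYMBOLS=\"",
                  paste(.state_to_symbol(0:(nsym - 1)), collapse = ""),
                  "\" MISSING=? GAP=-;"),
           "MATRIX", body, ";", "END;")
  if (length(ord))
    out <- c(out, "BEGIN ASSUMPTIONS;",
             paste0("TYPESET * default = ord: ", paste(ord, collapse = " "),
                    ";"), "END;")
  writeLines(out, path)
  invisible(path)
}
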
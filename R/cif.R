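# A small generic reader/writer for CIF-family text (mmCIF atom_site /
# cell / symmetry categories and monomer-library chem_comp dictionaries).
# Handles data blocks, name-value items, loop_ tables, single/double quoted
# strings, '#' comments and multi-line ';' text fields. Values are kept as
# character; '.' and '?' map to NA at conversion time.

.cif_tokenize_line <- function(line) {
  m <- gregexpr("('[^']*'|\"[^\"]*\"|\\S+)", line, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(line, list(m))[[1]]
  out <- character()
  for (tk in toks) {
    first <- substr(tk, 1, 1)
    if (first == "#") break
    if ((first == "'" || first == "\"") && nchar(tk) >= 2) {
      tk <- substr(tk, 2, nchar(tk) - 1)
      attr(tk, "quoted") <- TRUE
    }
    out <- c(out, tk)
  }
  out
}

.cif_tokenize <- function(lines) {
  tokens <- character()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      buf <- substring(line, 2)
      i <- i + 1L
      while (i <= n && !startsWith(lines[[i]], ";")) {
        buf <- c(buf, lines[[i]])
        i <- i + 1L
      }
      tokens <- c(tokens, paste(buf, collapse = "\n"))
      i <- i + 1L
      next
    }
    tokens <- c(tokens, .cif_tokenize_line(line))
    i <- i + 1L
  }
  tokens
}

#' Parse CIF text into data blocks
#'
#' @param text Character scalar (possibly multi-line) or vector of lines.
#' @return Named list of blocks; each block has `items` (named character
#'   vector) and `loops` (list of character data frames whose column names
#'   are the loop tags).
#' @keywords internal
cif_parse <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  tokens <- .cif_tokenize(lines)
  blocks <- list()
  cur_name <- NULL
  items <- character()
  loops <- list()
  flush_block <- function() {
    if (!is.null(cur_name)) {
      blocks[[cur_name]] <<- list(items = items, loops = loops)
    }
    items <<- character()
    loops <<- list()
  }
  i <- 1L
  n <- length(tokens)
  is_tag <- function(tk) startsWith(tk, "_")
  while (i <= n) {
    tk <- tokens[[i]]
    low <- tolower(tk)
    if (startsWith(low, "data_")) {
      flush_block()
      cur_name <- substring(tk, 6)
      if (!nzchar(cur_name)) cur_name <- "unnamed"
      i <- i + 1L
    } else if (low == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && is_tag(tokens[[i]])) {
        tags <- c(tags, tokens[[i]])
        i <- i + 1L
      }
      vals <- character()
      while (i <= n) {
        tk2 <- tokens[[i]]
        low2 <- tolower(tk2)
        if (is_tag(tk2) || low2 == "loop_" || startsWith(low2, "data_")) break
        vals <- c(vals, tk2)
        i <- i + 1L
      }
      if (length(tags)) {
        ncol <- length(tags)
        nrow <- length(vals) %/% ncol
        if (length(vals) %% ncol != 0) {
          abort(sprintf(
            "malformed CIF loop (%s...): %d values for %d columns",
            tags[1], length(vals), ncol
          ))
        }
        df <- as.data.frame(
          matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE),
          stringsAsFactors = FALSE
        )
        names(df) <- tags
        loops[[length(loops) + 1L]] <- df
      }
    } else if (is_tag(tk)) {
      if (i + 1L > n) abort(sprintf("CIF item %s has no value", tk))
      items[[tk]] <- tokens[[i + 1L]]
      i <- i + 2L
    } else {
      # stray token (e.g. global_); skip
      i <- i + 1L
    }
  }
  flush_block()
  blocks
}

# Find the loop of a block containing a given tag (exact match).
cif_find_loop <- function(block, tag) {
  for (lp in block$loops) if (tag %in% names(lp)) return(lp)
  NULL
}

cif_num <- function(x) {
  if (is.null(x)) return(NULL)
  x[x %in% c(".", "?")] <- NA_character_
  # strip su in parentheses, e.g. "1.525(12)"
  suppressWarnings(as.numeric(sub("\\(.*\\)$", "", x)))
}

cif_chr <- function(x) {
  if (is.null(x)) return(NULL)
  x[x %in% c(".", "?")] <- NA_character_
  x
}

.cif_quote <- function(x) {
  x <- as.character(x)
  needs <- grepl("[ \t']", x) | x == "" | grepl("^[_#$\\[\\]]", x)
  x[needs] <- paste0("\"", x[needs], "\"")
  x[is.na(x)] <- "."
  x
}

# Format a loop_ block with aligned columns.
cif_format_loop <- function(tags, columns) {
  stopifnot(length(tags) == length(columns))
  cols <- lapply(columns, .cif_quote)
  widths <- vapply(cols, function(cc) max(nchar(cc), 0L), integer(1))
  body <- if (length(cols[[1]])) {
    padded <- Map(function(cc, w) formatC(cc, width = -w), cols, widths)
    do.call(paste, padded)
  } else {
    character()
  }
  c("loop_", tags, body)
}
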
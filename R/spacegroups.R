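# Bundled space-group operator table (one standard setting per group,
# keyed by Hermann-Mauguin symbol) and the triplet algebra to turn
# "x,y,z"-style strings into fractional-coordinate affine operators.

.sg_env <- new.env(parent = emptyenv())

.sg_table <- function() {
  if (is.null(.sg_env$table)) {
    path <- system.file("extdata", "spacegroup_ops.tsv", package = "qmrestraints")
    tab <- read.delim(path, stringsAsFactors = FALSE)
    key <- function(x) gsub(" ", "", toupper(x))
    .sg_env$table <- tab
    # full Hermann-Mauguin symbols take precedence; short names (e.g.
    # "P 21" for "P 1 21 1") are accepted as aliases
    idx <- c(
      setNames(seq_len(nrow(tab)), key(tab$hm)),
      setNames(seq_len(nrow(tab)), key(tab$short))
    )
    .sg_env$index <- idx[!duplicated(names(idx))]
  }
  .sg_env$table
}

#' Parse a symmetry-operator triplet
#'
#' Converts a string such as `"-x+1/2,-y,z+1/2"` into a fractional-space
#' affine operator.
#'
#' @param triplet Operator triplet string.
#' @return List with `rot` (3x3 matrix) and `trans` (length-3 vector).
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) abort(sprintf("bad symmetry triplet: %s", triplet))
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (r in 1:3) {
    expr <- parts[[r]]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        rot[r, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        trans[r] <- trans[r] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[r] <- trans[r] + sign * as.numeric(body)
      } else {
        abort(sprintf("cannot parse symmetry term '%s' in %s", tm, triplet))
      }
    }
  }
  list(rot = rot, trans = trans)
}

symop_to_triplet <- function(op) {
  axes <- c("x", "y", "z")
  frac_str <- function(v) {
    v <- v %% 1
    if (abs(v) < 1e-9) return("")
    for (den in c(2, 3, 4, 6, 12)) {
      num <- v * den
      if (abs(num - round(num)) < 1e-9) return(sprintf("+%d/%d", round(num), den))
    }
    sprintf("%+g", v)
  }
  rows <- vapply(1:3, function(r) {
    s <- ""
    for (c in 1:3) {
      v <- op$rot[r, c]
      if (abs(v) > 1e-9) {
        s <- paste0(s, if (v > 0) if (nzchar(s)) "+" else "" else "-", axes[c])
      }
    }
    paste0(s, frac_str(op$trans[r]))
  }, character(1))
  paste(rows, collapse = ",")
}

.is_identity_op <- function(op) {
  all(abs(op$rot - diag(3)) < 1e-9) && all(abs(op$trans %% 1) < 1e-9)
}

#' Look up the symmetry operators of a space group
#'
#' Uses the bundled operator table (one standard setting per group, all 230
#' groups, including the 65 Sohncke groups relevant to macromolecular
#' crystals). Matching is case- and whitespace-insensitive, so `"P 21 21 21"`
#' and `"P212121"` both resolve.
#'
#' @param name Hermann-Mauguin symbol, e.g. `"P 21 21 21"`.
#' @return List of operators, each a list with `rot` and `trans` acting on
#'   fractional coordinates. The identity is always first.
#' @export
spacegroup_operators <- function(name) {
  tab <- .sg_table()
  i <- unname(.sg_env$index[gsub(" ", "", toupper(name))])
  if (is.null(i) || is.na(i)) {
    abort(sprintf("unknown space group '%s' and no explicit operators given", name))
  }
  trips <- strsplit(tab$triplets[[i]], ";", fixed = TRUE)[[1]]
  ops <- lapply(trips, parse_symop)
  ident <- vapply(ops, .is_identity_op, logical(1))
  c(ops[ident][1], ops[!ident])
}
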
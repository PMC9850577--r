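# package-level memoisation caches (canonical forms, fingerprints, oracle scores)
.cg_cache <- new.env(parent = emptyenv())

cg_cache_reset <- function() {
  rm(list = ls(.cg_cache, all.names = TRUE), envir = .cg_cache)
  invisible(NULL)
}

cg_cache_get_env <- function(name) {
  if (!exists(name, envir = .cg_cache, inherits = FALSE)) {
    assign(name, new.env(parent = emptyenv()), envir = .cg_cache)
  }
  get(name, envir = .cg_cache, inherits = FALSE)
}

#' Invalid-SMILES marker
#'
#' Invalidity is a value, not an exception: [canonicalize_smiles()] returns
#' `NA_character_` for text that cannot be parsed as a molecule.
#'
#' @export
SMILES_INVALID <- NA_character_

# Cheap syntactic screen applied before OpenBabel, which is lenient (it will
# silently repair, e.g., an unbalanced parenthesis). Rejects: empty strings,
# characters outside the SMILES alphabet, unbalanced () or [], and ring-bond
# labels that do not occur an even number of times.
smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\[\\]()=#%/\\\\.*:~-]", s)) return(FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  # bracket balance, no nesting of []
  depth_p <- 0L; depth_b <- 0L
  for (ch in chars) {
    if (ch == "(") depth_p <- depth_p + 1L
    else if (ch == ")") depth_p <- depth_p - 1L
    else if (ch == "[") depth_b <- depth_b + 1L
    else if (ch == "]") depth_b <- depth_b - 1L
    if (depth_p < 0L || depth_b < 0L || depth_b > 1L) return(FALSE)
  }
  if (depth_p != 0L || depth_b != 0L) return(FALSE)
  # ring-bond labels outside brackets must pair up
  bare <- gsub("\\[[^]]*\\]", "A", s)
  labels <- character(0)
  i <- 1L; n <- nchar(bare)
  while (i <= n) {
    ch <- substr(bare, i, i)
    if (ch == "%") {
      if (i + 2L > n) return(FALSE)
      labels <- c(labels, substr(bare, i + 1L, i + 2L))
      i <- i + 3L
    } else {
      if (grepl("[0-9]", ch)) labels <- c(labels, ch)
      i <- i + 1L
    }
  }
  if (length(labels) && any(table(labels) %% 2L != 0L)) return(FALSE)
  TRUE
}

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH", call. = FALSE)
  p
}

# One obabel invocation over a whole batch; row identity is carried in the
# SMILES title field so that molecules dropped by the parser can be detected.
obabel_canonicalize <- function(smiles) {
  if (!length(smiles)) return(character(0))
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), infile)
  out <- suppressWarnings(system2(
    obabel_path(), c(shQuote(infile), "-ocan", "-e"),
    stdout = TRUE, stderr = FALSE
  ))
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    parts <- strsplit(trimws(out), "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2L) {
        idx <- suppressWarnings(as.integer(p[[2L]]))
        if (!is.na(idx) && idx >= 1L && idx <= length(smiles)) res[idx] <- p[[1L]]
      }
    }
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Maps every chemically identical spelling of a molecule to one unique
#' canonical (aromatic-form) SMILES string. Unparsable text yields
#' `NA_character_` rather than an error, so validity can be treated as a
#' value. A syntactic screen rejects obviously malformed strings (unbalanced
#' parentheses or brackets, unmatched ring-bond labels) before the OpenBabel
#' parser, which would otherwise silently repair some of them.
#'
#' @param smiles character vector of SMILES strings (any spelling).
#' @return character vector of the same length: canonical SMILES, or
#'   `NA_character_` where the input is not a valid molecule.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO", "C(C"))  # "CCO" "CCO" NA
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  cache <- cg_cache_get_env("canonical")
  res <- rep(NA_character_, length(smiles))
  todo <- integer(0)
  for (i in seq_along(smiles)) {
    s <- smiles[[i]]
    if (is.na(s) || !smiles_syntax_ok(s)) next
    hit <- cache[[s]]
    if (!is.null(hit)) res[i] <- hit else todo <- c(todo, i)
  }
  if (length(todo)) {
    uniq <- unique(smiles[todo])
    canon <- obabel_canonicalize(uniq)
    names(canon) <- uniq
    for (i in todo) {
      v <- canon[[smiles[[i]]]]
      if (!is.na(v) && !nzchar(v)) v <- NA_character_
      cache[[smiles[[i]]]] <- v
      res[i] <- v
    }
  }
  res
}

#' Test SMILES validity
#'
#' A string is valid when [canonicalize_smiles()] produces a canonical form.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(canonicalize_smiles(smiles))
}

#' Read/write SMILES list files (one SMILES per line)
#'
#' @param path file path.
#' @return `read_smiles`: character vector of lines (blank lines dropped).
#' @export
read_smiles <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' @rdname read_smiles
#' @param smiles character vector to write.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
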
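# Property oracles: deterministic SMILES -> score maps.
#
# QED and penalized logP delegate to the reference cheminformatics toolkit
# (RDKit, driven in batches through the bundled helper script); activity or
# affinity predictors that live outside this package plug in as tabulated,
# external-command, or R-function oracles.

cg_python_path <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("python executable not found on PATH", call. = FALSE)
  p
}

cg_helper_script <- function() {
  p <- system.file("python", "property_scores.py", package = "contragen")
  if (!nzchar(p)) stop("bundled property_scores.py not found", call. = FALSE)
  p
}

# one python invocation per batch; NA where RDKit cannot parse
cg_python_scores <- function(smiles, property) {
  if (!length(smiles)) return(numeric(0))
  cache <- cg_cache_get_env(paste0("prop_", property))
  res <- rep(NA_real_, length(smiles))
  hit <- vapply(smiles, function(s) !is.null(cache[[s]]), logical(1))
  for (i in which(hit)) res[i] <- cache[[smiles[i]]]
  todo <- which(!hit)
  if (length(todo)) {
    uniq <- unique(smiles[todo])
    out <- suppressWarnings(system2(
      cg_python_path(), c(shQuote(cg_helper_script()), property),
      input = uniq, stdout = TRUE, stderr = FALSE
    ))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop("property helper failed (python/RDKit unavailable?)", call. = FALSE)
    }
    vals <- rep(NA_real_, length(uniq))
    for (line in out) {
      p <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(p) == 2L) {
        i <- suppressWarnings(as.integer(p[[1]]))
        if (!is.na(i)) vals[i] <- suppressWarnings(as.numeric(p[[2]]))
      }
    }
    for (j in seq_along(uniq)) cache[[uniq[j]]] <- vals[j]
    for (i in todo) res[i] <- cache[[smiles[i]]]
  }
  res
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Standard QED in `[0, 1]`, computed by the reference toolkit. Invariant to
#' the SMILES spelling of a molecule.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector of QED scores.
#' @export
qed_score <- function(smiles) {
  v <- cg_python_scores(smiles, "qed")
  if (anyNA(v)) {
    stop("invalid SMILES for QED: ", paste(smiles[is.na(v)], collapse = ", "),
         call. = FALSE)
  }
  v
}

#' Penalized logP
#'
#' The octanol-water partition coefficient penalized by synthetic
#' accessibility and oversized rings:
#' \deqn{pLogP(m) = logP(m) - SA(m) - \max(0, \mathrm{largestRing}(m) - 6).}
#' Two conventions circulate; the default is the unnormalized one above, and
#' `normalized = TRUE` selects the z-scored variant (each term standardized
#' by the usual ZINC250k moments).
#'
#' @param smiles character vector of valid SMILES.
#' @param normalized use the z-scored convention (default `FALSE`).
#' @return numeric vector of penalized logP scores.
#' @export
penalized_logp <- function(smiles, normalized = FALSE) {
  v <- cg_python_scores(smiles, if (normalized) "plogp_z" else "plogp")
  if (anyNA(v)) {
    stop("invalid SMILES for penalized logP: ",
         paste(smiles[is.na(v)], collapse = ", "), call. = FALSE)
  }
  v
}

#' Construct a property oracle
#'
#' A property oracle is a deterministic map from SMILES to a real score; it
#' raises an error (never a silent default) when asked to score something it
#' cannot. Kinds:
#' \describe{
#'   \item{`qed`}{drug-likeness via [qed_score()], range `[0, 1]`.}
#'   \item{`plogp`}{penalized logP via [penalized_logp()]; pass
#'     `normalized = TRUE` for the z-scored convention.}
#'   \item{`tabulated`}{finite SMILES-to-score table (the stand-in for
#'     external activity/affinity predictors); absent keys are an error.}
#'   \item{`external-command`}{shell command reading SMILES lines on stdin
#'     and printing one numeric per line.}
#'   \item{`function`}{an R function taking a character vector of SMILES and
#'     returning numeric scores; used for computable structural properties
#'     that must also score novel molecules.}
#' }
#'
#' @param kind one of `"qed"`, `"plogp"`, `"tabulated"`,
#'   `"external-command"`, `"function"`.
#' @param table for `tabulated`: named numeric vector, two-column
#'   data.frame (smiles, score), or path to a two-column TSV.
#' @param command for `external-command`: the command string.
#' @param fn for `function`: the scoring function.
#' @param name oracle identifier (defaults to `kind`).
#' @param range declared closed score interval, or `NULL` for unbounded.
#' @param normalized for `plogp`: z-scored convention flag.
#' @return an object of class `cg_oracle`.
#' @export
make_oracle <- function(kind, table = NULL, command = NULL, fn = NULL,
                        name = NULL, range = NULL, normalized = FALSE) {
  kind <- match.arg(kind, c("qed", "plogp", "tabulated", "external-command",
                            "function"))
  score_fn <- switch(kind,
    qed = {
      range <- c(0, 1)
      function(smiles) qed_score(smiles)
    },
    plogp = function(smiles) penalized_logp(smiles, normalized = normalized),
    tabulated = {
      tab <- read_score_table(table)
      function(smiles) {
        idx <- match(smiles, names(tab))
        missing <- is.na(idx)
        if (any(missing)) {
          canon <- canonicalize_smiles(smiles[missing])
          idx[missing] <- match(canon, names(tab))
        }
        if (anyNA(idx)) {
          stop("tabulated oracle has no entry for: ",
               paste(smiles[is.na(idx)], collapse = ", "), call. = FALSE)
        }
        unname(tab[idx])
      }
    },
    `external-command` = {
      if (is.null(command)) stop("external-command oracle needs `command`",
                                 call. = FALSE)
      function(smiles) {
        out <- system2("sh", c("-c", shQuote(command)), input = smiles,
                       stdout = TRUE, stderr = FALSE)
        v <- suppressWarnings(as.numeric(out))
        if (length(v) != length(smiles) || anyNA(v)) {
          stop("external oracle command failed or returned non-numeric output",
               call. = FALSE)
        }
        v
      }
    },
    `function` = {
      if (!is.function(fn)) stop("function oracle needs `fn`", call. = FALSE)
      function(smiles) {
        ok <- smiles_is_valid(smiles)
        if (!all(ok)) {
          stop("invalid SMILES for oracle: ",
               paste(smiles[!ok], collapse = ", "), call. = FALSE)
        }
        v <- fn(smiles)
        if (length(v) != length(smiles) || anyNA(v)) {
          stop("oracle function returned missing scores", call. = FALSE)
        }
        v
      }
    }
  )
  structure(list(name = if (is.null(name)) kind else name, kind = kind,
                 score = score_fn, range = range),
            class = "cg_oracle")
}

#' Score SMILES with an oracle
#'
#' @param oracle a `cg_oracle` from [make_oracle()].
#' @param smiles character vector.
#' @return numeric vector of scores.
#' @export
oracle_score <- function(oracle, smiles) {
  stopifnot(inherits(oracle, "cg_oracle"))
  oracle$score(smiles)
}

#' @export
print.cg_oracle <- function(x, ...) {
  rng <- if (is.null(x$range)) "unbounded" else
    sprintf("[%g, %g]", x$range[1], x$range[2])
  cat(sprintf("<property oracle '%s' (%s), range %s>\n", x$name, x$kind, rng))
  invisible(x)
}

#' Read/write a SMILES score table (two-column TSV: smiles, score)
#'
#' @param x a named numeric vector, a data.frame with columns smiles/score,
#'   or a file path.
#' @return named numeric vector keyed by SMILES.
#' @export
read_score_table <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    return(stats::setNames(as.numeric(x[[2]]), as.character(x[[1]])))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    df <- utils::read.table(x, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    if (ncol(df) < 2) stop("score table must have two columns", call. = FALSE)
    return(stats::setNames(as.numeric(df[[2]]), as.character(df[[1]])))
  }
  stop("cannot interpret score table", call. = FALSE)
}

#' @rdname read_score_table
#' @param tab named numeric vector.
#' @param path output TSV path.
#' @export
write_score_table <- function(tab, path) {
  utils::write.table(
    data.frame(smiles = names(tab), score = unname(tab)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
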
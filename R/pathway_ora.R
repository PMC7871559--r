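#' Pathway libraries for metabolite over-representation analysis
#'
#' A named collection of metabolite sets plus a background universe.
#' Every set must be a subset of the background; with no explicit
#' background the union of all sets is used (note this is the library
#' universe, not the assayed panel — supply the panel as `background`
#' if that is the universe you want).
#'
#' @param pathways named list of character vectors of metabolite ids
#'   (deduplicated; empty sets rejected).
#' @param background optional character vector of universe ids.
#' @return An object of class `pathway_library`.
#' @export
pathway_library <- function(pathways, background = NULL) {
  if (!is.list(pathways) || length(pathways) == 0L ||
      is.null(names(pathways)) || any(!nzchar(names(pathways))))
    stop("pathways must be a non-empty named list")
  pathways <- lapply(pathways, function(p) unique(as.character(p)))
  if (any(lengths(pathways) == 0L))
    stop("empty pathway set(s): ",
         paste(names(pathways)[lengths(pathways) == 0L], collapse = ", "))
  if (is.null(background)) {
    background <- sort(unique(unlist(pathways)))
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(unlist(pathways), background)
    if (length(stray))
      stop("pathway member(s) missing from background: ",
           paste(sort(unique(stray)), collapse = ", "))
  }
  structure(list(pathways = pathways, background = background),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat("Pathway library:", length(x$pathways), "sets over a background of",
      length(x$background), "metabolites\n")
  invisible(x)
}

#' Read a GMT pathway library
#'
#' Parses the tab-delimited GMT format (set name, description, then
#' members, one set per line). Duplicate members within a line are
#' deduplicated; lines with fewer than three fields raise a parse error
#' naming the line.
#'
#' @param path GMT file.
#' @param background optional universe: a character vector, or the path
#'   of a one-id-per-line file. Defaults to the union of all members.
#' @return A [pathway_library()].
#' @export
load_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": expected name, description and ",
           "at least one member")
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- readLines(background, warn = FALSE)
  pathway_library(sets, background)
}

# upper-tail hypergeometric P(X >= k) by exact summation of the pmf
# over the attainable overlap range; k = 0 gives exactly 1.
hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for enrichment of a candidate metabolite set
#' (e.g. the IVW-suggestive metabolites of a screen) against the
#' library background. For a pathway of size `K` in a background of
#' `N`, with `n` mapped candidates and `k` of them in the pathway, the
#' p-value is the exact upper tail `P(X >= k)` of the
#' hypergeometric(N, K, n) distribution. Candidates absent from the
#' background are logged and excluded from `n`. Raw p-values are
#' reported with a significance column at 0.05 — no multiple-testing
#' correction across pathways.
#'
#' @param candidates character vector of candidate metabolite ids.
#' @param library a [pathway_library()].
#' @return Data frame of class `ora_result`, sorted by ascending
#'   p-value: `pathway_id`, `k`, `K`, `n`, `N`, `pval`, `significant`.
#'   Attribute `"unmapped"` lists candidates outside the background.
#' @examples
#' lib <- pathway_library(list(glutathione = c("m1", "m2"),
#'                             urea = c("m3", "m4", "m5")),
#'                        background = paste0("m", 1:10))
#' ora_test(c("m1", "m2"), lib)
#' @export
ora_test <- function(candidates, library) {
  stopifnot(inherits(library, "pathway_library"))
  candidates <- unique(as.character(candidates))
  mapped <- intersect(candidates, library$background)
  if (length(mapped) == 0L)
    stop("no candidate metabolites map to the library background")
  N <- length(library$background)
  n <- length(mapped)
  out <- data.frame(
    pathway_id = names(library$pathways),
    k = vapply(library$pathways, function(p)
      length(intersect(mapped, p)), integer(1)),
    K = lengths(library$pathways),
    n = n, N = N, stringsAsFactors = FALSE)
  out$pval <- mapply(hyper_upper, out$k, out$K, out$n, out$N)
  out$significant <- out$pval < 0.05
  out <- out[order(out$pval, out$pathway_id), ]
  rownames(out) <- NULL
  structure(out, unmapped = setdiff(candidates, mapped),
            class = c("ora_result", "data.frame"))
}
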
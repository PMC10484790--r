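# HGVS.p-style protein variant notation: parsing and canonical formatting.
# Accepted dialects: three-letter ("p.Arg123Cys") and one-letter ("R123C")
# codes; missense, stop-gain (Ter/*/X), deletion, insertion and delins.
# Frameshifts are recognized and rejected as unsupported (they are not
# scorable at the protein level by this workflow).

.AA3 <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
          H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
          P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
          W = "Trp", Y = "Tyr")
.AA3_TO_1 <- stats::setNames(names(.AA3), .AA3)

aa_to_one <- function(x) {
  if (x %in% names(.AA3_TO_1)) return(unname(.AA3_TO_1[x]))
  if (toupper(x) %in% .AA) return(toupper(x))
  stop("unknown amino-acid code '", x, "'", call. = FALSE)
}

aa_run_to_one <- function(x) {
  # a run of residues in either three-letter (CamelCase) or one-letter code
  if (grepl("^([A-Z][a-z]{2})+$", x)) {
    parts <- regmatches(x, gregexpr("[A-Z][a-z]{2}", x))[[1]]
    paste(vapply(parts, aa_to_one, character(1)), collapse = "")
  } else if (grepl("^[A-Za-z]+$", x)) {
    paste(vapply(strsplit(toupper(x), "")[[1]], aa_to_one, character(1)),
          collapse = "")
  } else {
    stop("cannot parse residue run '", x, "'", call. = FALSE)
  }
}

.RES <- "([A-Z][a-z]{2}|[A-Z])"  # one residue, either code

#' Parse an HGVS.p-style protein variant notation
#'
#' @param notation A string such as `"p.Arg123Cys"`, `"R123C"`,
#'   `"p.Gln25Ter"`, `"p.Val600del"`, `"p.Lys10_Leu12delinsTrp"` or
#'   `"p.Lys10_Thr11insAla"`. The `"p."` prefix is optional.
#' @return A list of class `variant_record` with `kind` (one of
#'   `missense`, `stop_gain`, `deletion`, `insertion`, `delins`), the
#'   normalized coordinate fields, and `hgvs` (the canonical three-letter
#'   rendering). Frameshift notations raise an unsupported-variant error.
#' @examples
#' parse_variant("p.Arg123Cys")
#' parse_variant("p.Lys10_Leu12delinsTrp")
#' @export
parse_variant <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  x <- sub("^p\\.", "", trimws(notation))
  if (grepl("fs", x)) {
    stop("frameshift variant '", notation, "' is unsupported", call. = FALSE)
  }
  res <- .RES

  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)_", res,
                                    "([0-9]+)delins([A-Za-z]+)$"), x))[[1]]
  if (length(m)) {
    return(new_variant_record("delins",
                              start = as.integer(m[3]), end = as.integer(m[5]),
                              ref = aa_to_one(m[2]), ref_end = aa_to_one(m[4]),
                              inserted = aa_run_to_one(m[6])))
  }
  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)delins([A-Za-z]+)$"),
                             x))[[1]]
  if (length(m)) {
    return(new_variant_record("delins",
                              start = as.integer(m[3]), end = as.integer(m[3]),
                              ref = aa_to_one(m[2]), ref_end = aa_to_one(m[2]),
                              inserted = aa_run_to_one(m[4])))
  }
  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)_", res,
                                    "([0-9]+)del$"), x))[[1]]
  if (length(m)) {
    return(new_variant_record("deletion",
                              start = as.integer(m[3]), end = as.integer(m[5]),
                              ref = aa_to_one(m[2]), ref_end = aa_to_one(m[4])))
  }
  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)del$"), x))[[1]]
  if (length(m)) {
    return(new_variant_record("deletion",
                              start = as.integer(m[3]), end = as.integer(m[3]),
                              ref = aa_to_one(m[2]), ref_end = aa_to_one(m[2])))
  }
  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)_", res,
                                    "([0-9]+)ins([A-Za-z]+)$"), x))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[3]); p2 <- as.integer(m[5])
    if (p2 != p1 + 1L) {
      stop("insertion positions must be adjacent in '", notation, "'",
           call. = FALSE)
    }
    return(new_variant_record("insertion", start = p1, end = p2,
                              ref = aa_to_one(m[2]), ref_end = aa_to_one(m[4]),
                              inserted = aa_run_to_one(m[6]), anchor = p1))
  }
  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)(Ter|\\*|X)$"),
                             x))[[1]]
  if (length(m)) {
    return(new_variant_record("stop_gain", start = as.integer(m[3]),
                              end = as.integer(m[3]), ref = aa_to_one(m[2])))
  }
  m <- regmatches(x, regexec(paste0("^", res, "([0-9]+)", res, "$"), x))[[1]]
  if (length(m)) {
    ref <- aa_to_one(m[2]); alt <- aa_to_one(m[4])
    return(new_variant_record("missense", start = as.integer(m[3]),
                              end = as.integer(m[3]), ref = ref, alt = alt))
  }
  stop("cannot parse variant notation '", notation, "'", call. = FALSE)
}

new_variant_record <- function(kind, start, end, ref, ref_end = ref,
                               alt = NA_character_, inserted = "",
                               anchor = NA_integer_) {
  rec <- list(kind = kind, start = start, end = end, ref = ref,
              ref_end = ref_end, alt = alt, inserted = inserted,
              anchor = anchor)
  rec$hgvs <- format_variant(rec)
  class(rec) <- "variant_record"
  rec
}

#' Canonical three-letter HGVS.p rendering of a parsed variant
#'
#' @param rec A `variant_record` from [parse_variant()].
#' @return Character scalar; [parse_variant()] of the result round-trips.
#' @export
format_variant <- function(rec) {
  three <- function(one) unname(.AA3[one])
  runs3 <- function(run) {
    paste(vapply(strsplit(run, "")[[1]], three, character(1)), collapse = "")
  }
  switch(rec$kind,
    missense = sprintf("p.%s%d%s", three(rec$ref), rec$start, three(rec$alt)),
    stop_gain = sprintf("p.%s%dTer", three(rec$ref), rec$start),
    deletion = if (rec$start == rec$end) {
      sprintf("p.%s%ddel", three(rec$ref), rec$start)
    } else {
      sprintf("p.%s%d_%s%ddel", three(rec$ref), rec$start,
              three(rec$ref_end), rec$end)
    },
    insertion = sprintf("p.%s%d_%s%dins%s", three(rec$ref), rec$start,
                        three(rec$ref_end), rec$end, runs3(rec$inserted)),
    delins = if (rec$start == rec$end) {
      sprintf("p.%s%ddelins%s", three(rec$ref), rec$start,
              runs3(rec$inserted))
    } else {
      sprintf("p.%s%d_%s%ddelins%s", three(rec$ref), rec$start,
              three(rec$ref_end), rec$end, runs3(rec$inserted))
    },
    stop("unknown variant kind '", rec$kind, "'", call. = FALSE)
  )
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s (%s)\n", x$hgvs, x$kind))
  invisible(x)
}

# convert a parsed record into the scoring-layer object
as_indel_variant <- function(rec) {
  switch(rec$kind,
    deletion = indel_variant("deletion", start = rec$start, end = rec$end),
    insertion = indel_variant("insertion", inserted = rec$inserted,
                              anchor = rec$anchor),
    delins = indel_variant("delins", start = rec$start, end = rec$end,
                           inserted = rec$inserted),
    stop("'", rec$kind, "' is not an indel", call. = FALSE)
  )
}
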
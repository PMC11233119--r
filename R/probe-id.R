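#' Probe-ID suffix grammar
#'
#' Modern Infinium arrays (EPICv2, MSA) retain the legacy cg number as a
#' prefix and append a four-character design suffix after an underscore,
#' encoding strand orientation, bisulfite-conversion designator, Infinium
#' chemistry and a replicate index. The default grammar is
#' \code{[TB][CO][12][0-9]}: strand Top/Bottom, Converted/Opposite strand,
#' chemistry digit (1 = Infinium I, 2 = Infinium II), single-digit replicate
#' index. The grammar is a plain list so that other suffix dialects can be
#' swapped in without touching the parser.
#'
#' @param separator character separating prefix and suffix.
#' @param strand allowed strand codes.
#' @param conversion allowed conversion-designator codes.
#' @param chemistry named character vector mapping the chemistry digit to the
#'   chemistry label ("I"/"II").
#' @param classCodes accepted probe-class codes; anything else is rejected.
#'   Control probes are out of scope.
#' @return a list with the grammar fields plus compiled regular expressions
#'   \code{legacyRegex} and \code{suffixRegex}.
#' @examples
#' g <- suffixGrammar()
#' grepl(g$suffixRegex, "cg00000029_TC21")
#' @export
suffixGrammar <- function(separator = "_",
                          strand = c("T", "B"),
                          conversion = c("C", "O"),
                          chemistry = c("1" = "I", "2" = "II"),
                          classCodes = c("cg", "ch", "rs")) {
    cls <- paste0("(", paste(classCodes, collapse = "|"), ")")
    legacyRegex <- paste0("^", cls, "([0-9]+)$")
    suffixRegex <- paste0(
        "^", cls, "([0-9]+)", separator,
        "([", paste(strand, collapse = ""), "])",
        "([", paste(conversion, collapse = ""), "])",
        "([", paste(names(chemistry), collapse = ""), "])",
        "([0-9])$")
    list(separator = separator, strand = strand, conversion = conversion,
         chemistry = chemistry, classCodes = classCodes,
         legacyRegex = legacyRegex, suffixRegex = suffixRegex)
}

#' Parse Infinium probe identifiers
#'
#' Splits probe IDs into a cg-number prefix and (when present) the design
#' suffix fields. Legacy IDs ("cg00000029") are their own prefix; suffixed IDs
#' ("cg00000029_TC21") additionally carry strand, conversion designator,
#' Infinium chemistry and replicate index. Replicate probes are distinct
#' designs sharing one prefix; \code{\link{replicateGroups}} groups them.
#'
#' @param raw character vector of probe IDs.
#' @param grammar suffix grammar, see \code{\link{suffixGrammar}}.
#' @return a data.frame with one row per ID and columns \code{ProbeID},
#'   \code{Prefix}, \code{Strand}, \code{Conversion}, \code{Chemistry}
#'   ("I"/"II"), \code{ReplicateIndex}; suffix columns are \code{NA} for
#'   legacy IDs.
#' @examples
#' parseProbeID(c("cg00000029", "cg00000029_TC21"))
#' @seealso \code{\link{formatProbeID}} for the inverse.
#' @export
parseProbeID <- function(raw, grammar = suffixGrammar()) {
    if (length(raw) == 0L) {
        return(data.frame(ProbeID = character(), Prefix = character(),
                          Strand = character(), Conversion = character(),
                          Chemistry = character(),
                          ReplicateIndex = integer(),
                          stringsAsFactors = FALSE))
    }
    raw <- as.character(raw)
    if (anyNA(raw) || any(!nzchar(raw)))
        stop("probe IDs must be nonempty strings")
    legacy <- grepl(grammar$legacyRegex, raw)
    suffixed <- grepl(grammar$suffixRegex, raw)
    bad <- !legacy & !suffixed
    if (any(bad)) {
        offender <- raw[bad][1L]
        seg <- if (!grepl(paste0("^(",
                                 paste(grammar$classCodes, collapse = "|"),
                                 ")"), offender))
            "probe-class code" else "design suffix"
        stop("malformed probe ID '", offender, "': bad ", seg)
    }
    prefix <- raw
    strand <- conversion <- chem <- rep(NA_character_, length(raw))
    repidx <- rep(NA_integer_, length(raw))
    if (any(suffixed)) {
        m <- regmatches(raw[suffixed],
                        regexec(grammar$suffixRegex, raw[suffixed]))
        m <- do.call(rbind, m)
        prefix[suffixed] <- paste0(m[, 2L], m[, 3L])
        strand[suffixed] <- m[, 4L]
        conversion[suffixed] <- m[, 5L]
        chem[suffixed] <- unname(grammar$chemistry[m[, 6L]])
        repidx[suffixed] <- as.integer(m[, 7L])
    }
    data.frame(ProbeID = raw, Prefix = prefix, Strand = strand,
               Conversion = conversion, Chemistry = chem,
               ReplicateIndex = repidx, stringsAsFactors = FALSE)
}

#' Render parsed probe identifiers back to strings
#'
#' Inverse of \code{\link{parseProbeID}}: \code{formatProbeID(parseProbeID(x))}
#' equals \code{x} for any vector of well-formed IDs.
#'
#' @param parsed data.frame as returned by \code{\link{parseProbeID}}.
#' @param grammar suffix grammar, see \code{\link{suffixGrammar}}.
#' @return character vector of probe IDs.
#' @export
formatProbeID <- function(parsed, grammar = suffixGrammar()) {
    stopifnot(is.data.frame(parsed),
              all(c("Prefix", "Strand", "Conversion", "Chemistry",
                    "ReplicateIndex") %in% names(parsed)))
    hasSuffix <- !is.na(parsed$Strand)
    out <- parsed$Prefix
    if (any(hasSuffix)) {
        digit <- names(grammar$chemistry)[
            match(parsed$Chemistry[hasSuffix], grammar$chemistry)]
        out[hasSuffix] <- paste0(
            parsed$Prefix[hasSuffix], grammar$separator,
            parsed$Strand[hasSuffix], parsed$Conversion[hasSuffix],
            digit, parsed$ReplicateIndex[hasSuffix])
    }
    out
}

#' Extract the cg-number prefix of probe IDs
#'
#' @param ids character vector of probe IDs.
#' @param grammar suffix grammar.
#' @return character vector of prefixes.
#' @export
probePrefix <- function(ids, grammar = suffixGrammar()) {
    parseProbeID(ids, grammar)$Prefix
}
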
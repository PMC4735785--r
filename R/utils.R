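# Shared low-level helpers: chromosome ordering, strand algebra, DNA
# string primitives used by the simulator, mapper and resolver.

CHROM_LEVELS <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

#' Natural chromosome order rank
#'
#' Ranks chromosome names in the conventional order chr1 < ... < chr22 <
#' chrX < chrY; names outside that set sort after, alphabetically.
#'
#' @param chrom character vector of chromosome names.
#' @return integer-like numeric rank usable for sorting.
#' @keywords internal
chromRank <- function(chrom) {
    i <- match(chrom, CHROM_LEVELS)
    extra <- sort(unique(chrom[is.na(i)]))
    i[is.na(i)] <- length(CHROM_LEVELS) + match(chrom[is.na(i)], extra)
    i
}

flipStrand <- function(strand) {
    stopifnot(all(strand %in% c("F", "R")))
    ifelse(strand == "F", "R", "F")
}

#' Reverse complement of plain character DNA strings (vectorized)
#' @keywords internal
revcomp <- function(x) {
    if (!length(x)) return(character(0))
    as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(x)))
}

# round() uses banker's rounding; cohort summaries need conventional
# half-up rounding (5.0885 -> 5.1 at one decimal).
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

# strip thousands separators tolerated in the junction TSV dialect
stripCommas <- function(x) as.numeric(gsub(",", "", as.character(x)))

# --- 2-bit-per-base integer encoding -----------------------------------
# A/C/G/T -> 0:3; anything else -> NA. Used by the k-mer mapper and the
# assembler. k <= 26 keeps 4^k exactly representable in a double.

BASE_CODE <- local({
    v <- rep(NA_real_, 256)
    v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
    v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
    v[utf8ToInt("a")] <- 0; v[utf8ToInt("c")] <- 1
    v[utf8ToInt("g")] <- 2; v[utf8ToInt("t")] <- 3
    v
})

encodeDna <- function(x) BASE_CODE[utf8ToInt(x)]

decodeDna <- function(codes) {
    intToUtf8(c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"),
                utf8ToInt("T"))[codes + 1])
}

# complement in code space (A<->T, C<->G): 3 - code
revcompCodes <- function(codes) rev(3 - codes)

#' Rolling k-mer codes of an encoded sequence
#'
#' @param codes numeric vector of base codes (NA allowed; k-mers touching
#'   an NA get code NA).
#' @param k k-mer length (<= 26).
#' @return numeric vector of length `length(codes) - k + 1`.
#' @keywords internal
kmerCodes <- function(codes, k) {
    n <- length(codes)
    if (n < k) return(numeric(0))
    out <- numeric(n - k + 1)
    for (j in seq_len(k)) {
        out <- out + codes[j:(n - k + j)] * 4^(k - j)
    }
    out
}
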
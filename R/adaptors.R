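#' DamID adaptor and primer sequences
#'
#' The constant oligo sequences of the DamID library chemistry that appear
#' inside sequencing reads and must be removed before alignment: the DamID
#' PCR primer (sequenced at the 5' end of every amplicon-derived read) and
#' the Illumina index adaptor stem (read through at the 3' end when the
#' insert is shorter than the read). The 3' sequence carries the leading
#' `A` added to the stem by A-tailing, which is what a read-through read
#' actually contains.
#'
#' @return A list with elements `five_prime` and `three_prime`.
#' @export
damid_adaptors <- function() {
  list(
    five_prime  = "GGTCGCGGCCGAGGATC",
    three_prime = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  )
}

#' Illumina TruSeq-style index barcodes used for multiplexing
#'
#' Barcodes embedded in the index adaptors; the simulator records a
#' per-sample barcode in read identifiers only (demultiplexing is out of
#' scope).
#'
#' @return Named character vector, names `index1`, `index2`, ...
#' @export
damid_index_barcodes <- function() {
  c(index1 = "ATCACG", index2 = "CGATGT", index3 = "TTAGGC",
    index4 = "TGACCA", index5 = "ACAGTG", index6 = "GCCAAT",
    index7 = "CAGATC", index8 = "ACTTGA", index9 = "GATCAG",
    index10 = "TAGCTT", index11 = "GGCTAC", index12 = "CTTGTA")
}
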
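#' Synthetic CPP-like peptides (positive class)
#'
#' Sequences are drawn residue-by-residue with an Arg/Lys-enriched
#' composition (default sampling mass 0.25 + 0.20 = 0.45 on R/K, the
#' rest uniform) and lengths uniform over `lengthRange`. A rejection
#' step guarantees the cationic CPP profile per record: net formal
#' charge >= +2 and f\[Arg\] + f\[Lys\] >= 0.3. Duplicate sequences are
#' re-drawn so the emitted set is unique. Deterministic given `seed`.
#'
#' @param n number of peptides.
#' @param lengthRange inclusive length bounds inside \[5, 30\].
#' @param seed integer seed.
#' @param weights optional named residue sampling weights.
#' @param maxAttempts rejection cap per record (default 1e4).
#' @return a [PeptideSet-class] with `label = 1`, `source = "synthetic"`.
#' @examples
#' sampleCppLike(3, seed = 7)
#' @export
sampleCppLike <- function(n, lengthRange = c(5L, 30L), seed = 1L,
                          weights = NULL, maxAttempts = 10000L) {
    if (is.null(weights)) {
        weights <- stats::setNames(rep(0.55 / 18, 20), AA_ALPHABET20)
        weights[c("R", "K")] <- c(0.25, 0.20)
    }
    .sampleClass(n, lengthRange, seed, weights,
                 accept = function(s) {
                     ch <- computeChargeGroups(s)
                     a <- aacFractions(s)
                     ch[["NetC"]] >= 2 && (a[["f_Arg"]] + a[["f_Lys"]]) >= 0.3
                 },
                 prefix = "cpp", label = 1L, maxAttempts = maxAttempts)
}

#' Synthetic non-CPP peptides (negative class)
#'
#' Uniform residue composition with a rejection step capping the net
#' formal charge at +1, so the class-conditional NetC distributions of
#' the two generators are disjoint at the decision margin by
#' construction. Deterministic given `seed`.
#'
#' @inheritParams sampleCppLike
#' @return a [PeptideSet-class] with `label = 0`, `source = "synthetic"`.
#' @export
sampleNonCpp <- function(n, lengthRange = c(5L, 30L), seed = 1L,
                         maxAttempts = 10000L) {
    weights <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
    .sampleClass(n, lengthRange, seed, weights,
                 accept = function(s)
                     computeChargeGroups(s)[["NetC"]] <= 1,
                 prefix = "neg", label = 0L, maxAttempts = maxAttempts)
}

.sampleClass <- function(n, lengthRange, seed, weights, accept, prefix,
                         label, maxAttempts) {
    stopifnot(lengthRange[1L] >= 5L, lengthRange[2L] <= 30L,
              lengthRange[1L] <= lengthRange[2L])
    seqs <- character(0)
    .withSeed(seed, {
        for (i in seq_len(n)) {
            attempt <- 0L
            repeat {
                attempt <- attempt + 1L
                if (attempt > maxAttempts)
                    stop("rejection cap exceeded: constraints look ",
                         "infeasible for the requested composition")
                L <- sample(seq(lengthRange[1L], lengthRange[2L]), 1L)
                s <- paste(sample(names(weights), L, replace = TRUE,
                                  prob = weights), collapse = "")
                if (accept(s) && !s %in% seqs) break
            }
            seqs[i] <- s
        }
    })
    PeptideSet(seqs, ids = sprintf("%s_%04d", prefix, seq_len(n)),
               source = "synthetic", label = label)
}

#' Balanced (or imbalanced) labelled synthetic benchmark
#'
#' Concatenates a CPP-like and a non-CPP sample, shuffles the records
#' with the seed, and returns the dataset with a manifest recording the
#' full configuration so any benchmark can be regenerated byte-identically.
#'
#' @param nPos,nNeg class sizes (each >= 10).
#' @param lengthRange inclusive length bounds inside \[5, 30\].
#' @param seed integer seed driving both generators and the shuffle.
#' @return list with `peptides` (a [PeptideSet-class]) and `manifest`.
#' @examples
#' bench <- makeBenchmark(10, 10, seed = 7)
#' table(peptideLabels(bench$peptides))
#' @export
makeBenchmark <- function(nPos, nNeg, lengthRange = c(5L, 30L), seed = 7L) {
    stopifnot(nPos >= 10L, nNeg >= 10L)
    pos <- sampleCppLike(nPos, lengthRange, seed = seed)
    neg <- sampleNonCpp(nNeg, lengthRange, seed = seed + 1L)
    all <- combinePeptideSets(pos, neg)
    ord <- .withSeed(seed + 2L, sample(length(all)))
    ps <- all[ord]
    manifest <- list(generator = "pepCross::makeBenchmark",
                     nPos = nPos, nNeg = nNeg,
                     lengthRange = as.integer(lengthRange),
                     seed = as.integer(seed),
                     posRule = "NetC >= +2 and f[Arg]+f[Lys] >= 0.3",
                     negRule = "NetC <= +1",
                     duplicatesRedrawn = TRUE)
    list(peptides = ps, manifest = manifest)
}

#' Write a benchmark to FASTA + label CSV + JSON manifest
#'
#' @param bench result of [makeBenchmark()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeBenchmark <- function(bench, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ps <- bench$peptides
    writeFastaPeptides(ps, file.path(dir, "peptides.fasta"))
    utils::write.csv(
        data.frame(id = peptideIds(ps), sequence = peptideSequences(ps),
                   label = peptideLabels(ps)),
        file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}
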
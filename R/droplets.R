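#' Classify one channel's droplets with two amplitude thresholds
#'
#' Applies the assay's two-threshold scheme to a single fluorescence channel:
#' droplets with amplitude strictly greater than \code{tTotal} are positive,
#' and positives strictly greater than \code{tAllele} form the high-amplitude
#' cluster of the fluorescently labeled allele. Droplets exactly at a
#' threshold are below it (the boundary convention is strict \code{>}).
#' Intermediate-amplitude 'rain' droplets are assigned purely by the
#' thresholds; no cluster-model rescue is attempted.
#'
#' @param well A [DropletWell-class].
#' @param thresholds A [ChannelThresholds-class] whose \code{cpg} names a
#'   channel present in the well.
#' @return A [ClusterCounts-class] object; counts always satisfy
#'   \code{nNegative + nPositiveTotal == nTotal}.
#' @export
#' @examples
#' w <- DropletWell("A01", list(ELOVL2 = c(1000, 1500, 3000, 7000)))
#' classifyDroplets(w, ChannelThresholds("ELOVL2", 2000, 6000))
classifyDroplets <- function(well, thresholds) {
  stopifnot(is(well, "DropletWell"), is(thresholds, "ChannelThresholds"))
  a <- amplitudes(well, thresholds@cpg)
  if (length(a) == 0L)
    stop("empty amplitude list for channel '", thresholds@cpg, "'")
  nPos <- sum(a > thresholds@tTotal)
  nAllele <- sum(a > thresholds@tAllele)
  ClusterCounts(thresholds@cpg, nTotal = length(a),
                nNegative = length(a) - nPos, nPositiveTotal = nPos,
                nAllele = nAllele, labeled = thresholds@labeledAllele)
}

#' Methylation fraction from cluster counts
#'
#' Computes the CpG methylation fraction from one channel's droplet counts
#' using the assay's orientation-specific formulas: for channels labeling the
#' methylated allele, methylated droplets over total informative droplets,
#' \eqn{M/(M+U)}; for channels labeling the unmethylated allele,
#' \eqn{1 - U/(M+U)}. The two are algebraically the same quantity, so the
#' result depends only on \eqn{(M, U)}, not on the labeling orientation.
#'
#' @param counts A [ClusterCounts-class] with at least one positive droplet.
#' @param rule A [QCRule-class] used for the attached QC record.
#' @return A [MethylationResult-class] carrying beta, the \code{(M, U)}
#'   counts, and the channel's [PoissonQuant-class] QC record.
#' @export
#' @examples
#' cc <- ClusterCounts("ELOVL2", 20000, 19000, 1000, 300)
#' methylationFraction(cc)
methylationFraction <- function(counts, rule = QCRule()) {
  stopifnot(is(counts, "ClusterCounts"))
  M <- methylatedCount(counts)
  U <- unmethylatedCount(counts)
  if (M + U == 0L)
    stop("no positive droplets in channel '", counts@cpg,
         "': methylation undefined")
  beta <- if (counts@labeledAllele == "methylated") M / (M + U)
          else 1 - U / (M + U)
  new("MethylationResult", cpg = counts@cpg, beta = beta,
      M = as.integer(M), U = as.integer(U), qc = qcEvaluate(counts, rule))
}

#' Quantify all channels of one well
#'
#' Per-well driver: classifies each channel with its thresholds and computes
#' its methylation fraction and Poisson QC record. Channel failures (e.g. an
#' all-negative channel) do not abort the well; they are returned as error
#' entries naming the failing CpG.
#'
#' @param well A [DropletWell-class].
#' @param thresholds List of [ChannelThresholds-class], exactly one per
#'   channel present in the well.
#' @param rule A [QCRule-class].
#' @return Named list, one entry per CpG: a [MethylationResult-class], or a
#'   \code{condition} object for channels that failed.
#' @export
quantifyWell <- function(well, thresholds, rule = QCRule()) {
  stopifnot(is(well, "DropletWell"))
  if (is(thresholds, "ChannelThresholds")) thresholds <- list(thresholds)
  cpgs <- vapply(thresholds, function(t) t@cpg, character(1))
  if (anyDuplicated(cpgs))
    stop("duplicate threshold entries for: ",
         paste(unique(cpgs[duplicated(cpgs)]), collapse = ", "))
  missing <- setdiff(channelNames(well), cpgs)
  if (length(missing))
    stop("no thresholds supplied for channel(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(thresholds, function(t) {
    tryCatch(methylationFraction(classifyDroplets(well, t), rule),
             error = function(e) {
               simpleError(sprintf("[%s] %s", t@cpg, conditionMessage(e)))
             })
  })
  names(out) <- cpgs
  out
}

#' Read a droplet amplitude CSV
#'
#' Reads droplet amplitude exports in either of two dialects, auto-detected
#' from the header: long format with columns \code{well,channel,amplitude}
#' (one row per droplet per channel), or wide format with a \code{well}
#' column followed by one amplitude column per channel.
#'
#' @param path CSV file path.
#' @return Named list of [DropletWell-class] objects, one per well.
#' @export
readDroplets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"well" %in% names(df))
    stop("droplet CSV must have a 'well' column")
  if (all(c("channel", "amplitude") %in% names(df))) {
    wells <- split(df, df$well)
    out <- lapply(wells, function(d) {
      amps <- split(as.numeric(d$amplitude), d$channel)
      n <- lengths(amps)
      if (length(unique(n)) != 1L)
        stop("well '", d$well[1L], "': channels have unequal droplet counts")
      DropletWell(d$well[1L], amps)
    })
  } else {
    chans <- setdiff(names(df), "well")
    if (!length(chans)) stop("wide droplet CSV has no channel columns")
    wells <- split(df, df$well)
    out <- lapply(wells, function(d)
      DropletWell(d$well[1L], lapply(d[chans], as.numeric)))
  }
  out[order(names(out))]
}

#' Write a droplet amplitude CSV (long dialect)
#'
#' @param wells List of [DropletWell-class] objects.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeDroplets <- function(wells, path) {
  if (is(wells, "DropletWell")) wells <- list(wells)
  rows <- do.call(rbind, lapply(wells, function(w) {
    do.call(rbind, lapply(channelNames(w), function(ch)
      data.frame(well = wellId(w), channel = ch,
                 amplitude = amplitudes(w, ch))))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a threshold configuration CSV
#'
#' One record per CpG with columns \code{cpg,t_total,t_allele,labeled_allele}
#' (\code{labeled_allele} optional for panel CpGs, where the orientation is
#' known).
#'
#' @param path CSV file path.
#' @return List of [ChannelThresholds-class] objects.
#' @export
readThresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cpg", "t_total", "t_allele")
  if (!all(need %in% names(df)))
    stop("threshold CSV needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    lab <- if ("labeled_allele" %in% names(df)) df$labeled_allele[i]
           else unname(labeledAllele(df$cpg[i]))
    ChannelThresholds(df$cpg[i], df$t_total[i], df$t_allele[i], lab)
  })
}

#' Quantify many wells into a tidy results table
#'
#' Runs [quantifyWell()] over a set of wells and flattens the results to one
#' row per well per CpG, with the methylation estimate, droplet counts, and
#' Poisson QC columns. Failed channels yield a row with \code{NA} values and
#' the error message.
#'
#' @param wells List of [DropletWell-class] objects (as from [readDroplets()]).
#' @param thresholds List of [ChannelThresholds-class].
#' @param rule A [QCRule-class].
#' @return \code{data.frame} with columns \code{well, cpg, beta, M, U,
#'   n_total, n_positive, p_positive, lambda, copies, single_fraction,
#'   qc_pass, error}.
#' @export
quantifyWells <- function(wells, thresholds, rule = QCRule()) {
  if (is(wells, "DropletWell")) wells <- list(wells)
  rows <- lapply(wells, function(w) {
    res <- quantifyWell(w, thresholds, rule)
    do.call(rbind, lapply(names(res), function(cpg) {
      r <- res[[cpg]]
      if (is(r, "condition"))
        data.frame(well = wellId(w), cpg = cpg, beta = NA_real_,
                   M = NA_integer_, U = NA_integer_,
                   n_total = dropletCount(w), n_positive = NA_integer_,
                   p_positive = NA_real_, lambda = NA_real_,
                   copies = NA_real_, single_fraction = NA_real_,
                   qc_pass = FALSE, error = conditionMessage(r))
      else
        data.frame(well = wellId(w), cpg = cpg, beta = r@beta, M = r@M,
                   U = r@U, n_total = dropletCount(w),
                   n_positive = r@M + r@U + 0L,
                   p_positive = r@qc@pPositive, lambda = r@qc@lambda,
                   copies = r@qc@copies, single_fraction = r@qc@singleFraction,
                   qc_pass = r@qc@pass, error = NA_character_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
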
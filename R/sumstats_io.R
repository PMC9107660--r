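#' Construct a summary-statistics object
#'
#' A `sumstats` object is a data.frame of per-SNP association records for a
#' single trait — the common currency of every stage of the pipeline — with
#' the trait label and type attached as attributes.  Columns: `rsid`,
#' `chrom` (1-22), `pos` (bp, 1-based), `a1` (effect allele), `a2` (other
#' allele), `beta`, `se`, `pval`, `n`, `z`, and optionally `eaf`.
#'
#' On construction, `z` is derived as `beta/se` when absent and checked
#' against `beta/se` when present; a missing `pval` is recomputed from `|z|`
#' under the two-sided standard normal; rows with non-positive `se` or
#' non-finite effect estimates are dropped with a message.
#'
#' @param df data.frame with at least rsid, chrom, pos, a1, a2, beta, se, n.
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"` (binary effects are
#'   log-odds).
#' @return A `sumstats` object (data.frame subclass).
#' @export
sumstats <- function(df, trait_label = "trait", trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  needed <- c("rsid", "chrom", "pos", "a1", "a2", "beta", "se", "n")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("sumstats: missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$rsid  <- as.character(df$rsid)
  df$chrom <- as.integer(df$chrom)
  df$pos   <- as.integer(df$pos)
  df$a1    <- toupper(as.character(df$a1))
  df$a2    <- toupper(as.character(df$a2))
  for (col in intersect(c("beta", "se", "pval", "n", "z", "eaf"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }

  bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
    !is.finite(df$n) | df$n <= 0 | df$a1 == df$a2
  if (any(bad)) {
    message("sumstats: dropping ", sum(bad), " row(s) with invalid se/beta/n/alleles")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("sumstats: no valid rows remain")

  if (is.null(df$z)) {
    df$z <- df$beta / df$se
  } else {
    have <- is.finite(df$z)
    df$z[!have] <- df$beta[!have] / df$se[!have]
    off <- abs(df$z[have] - df$beta[have] / df$se[have]) > 1e-6 * pmax(1, abs(df$z[have]))
    if (any(off)) {
      warning("sumstats: ", sum(off), " row(s) have z inconsistent with beta/se; z kept as given")
    }
  }
  if (is.null(df$pval)) {
    df$pval <- 2 * stats::pnorm(-abs(df$z))
  } else {
    miss <- !is.finite(df$pval)
    df$pval[miss] <- 2 * stats::pnorm(-abs(df$z[miss]))
  }
  df$pval <- pmin(pmax(df$pval, .Machine$double.xmin), 1)
  if (is.null(df$eaf)) df$eaf <- NA_real_

  keep <- c("rsid", "chrom", "pos", "a1", "a2", "beta", "se", "pval", "n", "z", "eaf")
  df <- df[, keep]
  rownames(df) <- NULL
  structure(df,
    trait_label = trait_label, trait_type = trait_type,
    class = c("sumstats", "data.frame")
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf(
    "GWAS summary statistics: %s (%s), %d SNPs\n",
    attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)
  ))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Trait label of a sumstats object
#' @param s sumstats object.
#' @return Character scalar.
#' @export
trait_label <- function(s) attr(s, "trait_label")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads tab- or whitespace-delimited summary statistics (gzip transparently
#' supported) with a configurable column map, and returns a validated
#' [sumstats] object.  Rows with unparseable numeric fields are dropped and
#' counted in a message.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`SNP, CHR, BP, A1, A2, BETA, SE, P, N, Z, EAF`) to the file's header
#'   names.  Defaults to the identity map for these canonical names.
#' @param trait_label trait name to attach.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_label = basename(path),
                          trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("read_sumstats: file not found: ", path)
  dat <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  if (nrow(dat) == 0L) stop("read_sumstats: empty file: ", path)

  canon <- c(SNP = "rsid", CHR = "chrom", BP = "pos", A1 = "a1", A2 = "a2",
             BETA = "beta", SE = "se", P = "pval", N = "n", Z = "z", EAF = "eaf")
  cmap <- stats::setNames(names(canon), names(canon)) # identity by default
  if (!is.null(column_map)) cmap[names(column_map)] <- unname(column_map)

  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "N")
  absent <- mandatory[!(cmap[mandatory] %in% names(dat))]
  if (length(absent)) {
    stop("read_sumstats: mandatory column(s) not found in file: ",
         paste(cmap[absent], collapse = ", "))
  }

  out <- data.frame(row.names = seq_len(nrow(dat)))
  for (key in names(canon)) {
    src <- cmap[[key]]
    if (src %in% names(dat)) out[[canon[[key]]]] <- dat[[src]]
  }
  n0 <- nrow(out)
  num_cols <- intersect(c("beta", "se", "pval", "n", "z", "eaf"), names(out))
  for (col in num_cols) out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  parse_ok <- rowSums(is.na(out[, c("beta", "se"), drop = FALSE])) == 0
  if (any(!parse_ok)) {
    message("read_sumstats: dropped ", sum(!parse_ok), " row(s) with unparseable numerics")
    out <- out[parse_ok, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("read_sumstats: no parseable rows in ", path)
  sumstats(out, trait_label = trait_label, trait_type = trait_type)
}

#' Write summary statistics to a tab-delimited file
#'
#' Inverse of [read_sumstats()]; numeric fields are written at full double
#' precision so a write/read round trip preserves them to 1e-12.
#'
#' @param s sumstats object.
#' @param path output path (".gz" suffix gives gzip output).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  out <- as.data.frame(s)
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N", "Z", "EAF")
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Quality-control summary statistics
#'
#' Removes SNPs whose identifier is not an rs label (`rs` followed by
#' digits) and removes *all* copies of any duplicated rsID (duplicates
#' cannot be adjudicated, so the conservative drop-all policy is used).
#' Idempotent.
#'
#' @param s sumstats object.
#' @return QC'd sumstats with a `qc_report` attribute: counts removed per
#'   rule.
#' @export
qc_sumstats <- function(s) {
  stopifnot(inherits(s, "sumstats"))
  if (nrow(s) == 0L) stop("qc_sumstats: empty input")
  no_rs <- !grepl("^rs[0-9]+$", s$rsid)
  s1 <- s[!no_rs, , drop = FALSE]
  dup_ids <- unique(s1$rsid[duplicated(s1$rsid)])
  is_dup <- s1$rsid %in% dup_ids
  s2 <- s1[!is_dup, , drop = FALSE]
  if (nrow(s2) == 0L) stop("qc_sumstats: all rows removed by QC")
  report <- c(no_rs_label = sum(no_rs), duplicated = sum(is_dup),
              retained = nrow(s2))
  out <- restore_sumstats(s2, s)
  attr(out, "qc_report") <- report
  out
}

#' Exclude a genomic region from summary statistics
#'
#' Removes SNPs with `chrom == chrom` and `start <= pos <= end` (1-based,
#' closed interval).  The default window is the extended MHC region on
#' chromosome 6 (25-34 Mb), conventionally excluded before LD score
#' regression because its long-range LD violates the model.
#'
#' @param s sumstats object.
#' @param chrom chromosome of the window.
#' @param start,end window bounds in bp, closed.
#' @return Filtered sumstats.
#' @export
exclude_region <- function(s, chrom = 6L, start = 25e6, end = 34e6) {
  stopifnot(inherits(s, "sumstats"), start <= end)
  hit <- s$chrom == chrom & s$pos >= start & s$pos <= end
  out <- restore_sumstats(s[!hit, , drop = FALSE], s)
  if (nrow(out) == 0L) warning("exclude_region: all SNPs removed")
  out
}

#' Harmonize a pair of summary-statistics sets to common SNPs and alleles
#'
#' Intersects the two sets on rsID, aligns the outcome to the exposure's
#' effect allele (swapping alleles and flipping the signs of `beta` and `z`
#' where the outcome's alleles are reversed), removes strand-ambiguous
#' palindromic SNPs (A/T and C/G) unless `keep_palindromic = TRUE` and both
#' sets carry allele frequencies clearly away from 0.5
#' (`|eaf - 0.5| > eaf_margin`), and removes SNPs whose alleles cannot be
#' reconciled.  Both outputs have identical SNP order.
#'
#' @param exposure,outcome sumstats objects that have passed [qc_sumstats()].
#' @param keep_palindromic retain palindromic SNPs when frequency-alignable.
#' @param eaf_margin minimum distance of eaf from 0.5 for frequency
#'   alignment of palindromic SNPs.
#' @return List with elements `exposure` and `outcome` (aligned sumstats)
#'   and `report` (counts removed per rule).
#' @export
harmonize_pair <- function(exposure, outcome, keep_palindromic = FALSE,
                           eaf_margin = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  common <- intersect(exposure$rsid, outcome$rsid)
  if (length(common) == 0L) stop("harmonize_pair: no shared SNPs")
  e <- exposure[match(common, exposure$rsid), , drop = FALSE]
  o <- outcome[match(common, outcome$rsid), , drop = FALSE]

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- e$a1 == comp[e$a2]
  same  <- e$a1 == o$a1 & e$a2 == o$a2
  swap  <- e$a1 == o$a2 & e$a2 == o$a1

  n_irrec <- sum(!same & !swap)
  keep <- (same | swap) & !palin
  n_palin_dropped <- sum(palin & (same | swap))
  if (keep_palindromic) {
    freq_ok <- palin & (same | swap) &
      is.finite(e$eaf) & is.finite(o$eaf) &
      abs(e$eaf - 0.5) > eaf_margin & abs(o$eaf - 0.5) > eaf_margin
    # same-strand frequencies must agree after any allele swap
    of <- ifelse(swap, 1 - o$eaf, o$eaf)
    strand_ok <- freq_ok & (abs(e$eaf - of) < abs(e$eaf - (1 - of)))
    keep <- ((same | swap) & !palin) | strand_ok
    n_palin_dropped <- sum(palin & (same | swap) & !strand_ok)
  }

  e2 <- e[keep, , drop = FALSE]
  o2 <- o[keep, , drop = FALSE]
  flip <- swap[keep]
  if (any(flip)) {
    tmp <- o2$a1[flip]
    o2$a1[flip] <- o2$a2[flip]
    o2$a2[flip] <- tmp
    o2$beta[flip] <- -o2$beta[flip]
    o2$z[flip] <- -o2$z[flip]
    o2$eaf[flip] <- 1 - o2$eaf[flip]
  }
  if (nrow(e2) == 0L) stop("harmonize_pair: no SNPs remain after harmonization")
  list(
    exposure = restore_sumstats(e2, exposure),
    outcome  = restore_sumstats(o2, outcome),
    report = c(shared = length(common), irreconcilable = n_irrec,
               palindromic_removed = n_palin_dropped, retained = nrow(e2))
  )
}

#' Read a gene annotation
#'
#' Accepts a BED-like tab-delimited file (`chrom`, `start`, `end`,
#' `gene_id`; 1-based closed intervals) and returns a data.frame usable by
#' [map_genes_to_snps()].
#'
#' @param path file path.
#' @return data.frame with columns gene_id, chrom, start, end.
#' @export
read_gene_annotation <- function(path) {
  dat <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dat) < 4) stop("read_gene_annotation: need chrom, start, end, gene_id")
  out <- data.frame(
    gene_id = as.character(dat[[4]]), chrom = as.integer(dat[[1]]),
    start = as.integer(dat[[2]]), end = as.integer(dat[[3]]),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("read_gene_annotation: start > end")
  out
}

#' Map genes to member SNPs
#'
#' Assigns each SNP in `s` to every gene whose (optionally widened)
#' interval contains it; a SNP may belong to multiple genes.  Genes with no
#' member SNPs are dropped.
#'
#' @param genes data.frame from [read_gene_annotation()] or equivalent.
#' @param s sumstats object supplying SNP positions.
#' @param window_kb symmetric window added to each gene interval (kb);
#'   default 0.
#' @return Named list of character vectors of rsIDs, one per gene.
#' @export
map_genes_to_snps <- function(genes, s, window_kb = 0) {
  w <- window_kb * 1000
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- s$chrom == genes$chrom[i] &
      s$pos >= genes$start[i] - w & s$pos <= genes$end[i] + w
    s$rsid[hit]
  })
  names(out) <- genes$gene_id
  out[vapply(out, length, 1L) > 0L]
}

# reattach sumstats class/attributes after a data.frame subset
restore_sumstats <- function(df, template) {
  rownames(df) <- NULL
  structure(as.data.frame(df),
    trait_label = attr(template, "trait_label"),
    trait_type = attr(template, "trait_type"),
    class = c("sumstats", "data.frame")
  )
}
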
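# Aligned haplotype data: reading, validation, site classification and
# polarization against an outgroup.  Coordinates are 0-based half-open
# internally; log messages use 1-based column numbers.

.VALID_CODES <- c("A", "C", "G", "T", "N", "-")
.MISSING_CODES <- c("N", "-")

# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
.CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.translate_codon <- function(codon) {
  aa <- .CODON_TABLE[paste(codon, collapse = "")]
  if (is.na(aa)) NA_character_ else unname(aa)
}

#' Construct a locus alignment object
#'
#' A `locus_alignment` holds the phased haplotypes of one gene fragment as a
#' character matrix (rows = haplotypes, columns = alignment positions, codes
#' `A`, `C`, `G`, `T`, `N`, `-`), together with an optional gene model giving
#' exon intervals and the reading frame.  All downstream statistics and the
#' haplogroup machinery consume this container.
#'
#' @param mat Character matrix of allele codes; rownames are haplotype ids.
#' @param locus_id Locus identifier string.
#' @param gene_model `NULL` or a data.frame with columns `exon_start`,
#'   `exon_end` (0-based half-open, alignment coordinates) and `frame`
#'   (0, 1 or 2: offset of the exon's first base within its codon).
#' @param region Chromosomal context tag, one of `"inside_2La"`,
#'   `"near_2La"`, `"collinear_2L"`, `"other_arm"`.
#' @return An object of class `locus_alignment` with elements `locus_id`,
#'   `region`, `mat`, `gene_model`, `n` (haplotypes) and `L` (columns).
#' @export
locus_alignment <- function(mat, locus_id = "locus", gene_model = NULL,
                            region = c("other_arm", "inside_2La", "near_2La",
                                       "collinear_2L")) {
  region <- match.arg(region)
  if (!is.matrix(mat) || !is.character(mat))
    stop("'mat' must be a character matrix of allele codes")
  mat[] <- toupper(mat)
  bad <- which(!(mat %in% .VALID_CODES))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(mat))
    stop(sprintf("illegal character '%s' in record '%s' at column %d",
                 mat[bad[1]], rownames(mat)[i[1]], i[2]))
  }
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("hap", seq_len(nrow(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("haplotype ids must be unique")
  gm <- .validate_gene_model(gene_model, ncol(mat))
  structure(list(locus_id = locus_id, region = region, mat = mat,
                 gene_model = gm, n = nrow(mat), L = ncol(mat)),
            class = "locus_alignment")
}

.validate_gene_model <- function(gene_model, L) {
  if (is.null(gene_model)) return(NULL)
  gm <- as.data.frame(gene_model)
  need <- c("exon_start", "exon_end", "frame")
  if (!all(need %in% names(gm)))
    stop("gene model needs columns exon_start, exon_end, frame")
  gm <- gm[order(gm$exon_start), need, drop = FALSE]
  if (any(gm$exon_start < 0L) || any(gm$exon_end > L) ||
      any(gm$exon_end <= gm$exon_start))
    stop("exon intervals must be non-empty and within [0, L)")
  if (nrow(gm) > 1 &&
      any(gm$exon_start[-1] < gm$exon_end[-nrow(gm)]))
    stop("exon intervals must be non-overlapping")
  if (!all(gm$frame %in% 0:2))
    stop("frame must be 0, 1 or 2")
  gm
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d haplotypes x %d bp (%s), %d exon(s)\n",
              x$locus_id, x$n, x$L, x$region,
              if (is.null(x$gene_model)) 0L else nrow(x$gene_model)))
  invisible(x)
}

#' Read an aligned FASTA file into a locus alignment
#'
#' Records must all have the same length (the data are a multiple sequence
#' alignment, not raw reads).  Lowercase letters are normalized to uppercase.
#'
#' @param path Path to an aligned FASTA file.
#' @inheritParams locus_alignment
#' @return A [locus_alignment()].
#' @export
read_fasta_alignment <- function(path, gene_model = NULL,
                                 locus_id = tools::file_path_sans_ext(basename(path)),
                                 region = "other_arm") {
  if (!file.exists(path) || file.size(path) == 0)
    stop(sprintf("no records in '%s'", path))
  seqs <- ape::read.FASTA(path, type = "DNA")
  if (length(seqs) == 0) stop(sprintf("no records in '%s'", path))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    off <- names(seqs)[which(lens != lens[1])[1]]
    stop(sprintf("alignment error: record '%s' has length %d, expected %d",
                 off, lens[names(seqs) == off][1], lens[1]))
  }
  mat <- toupper(as.character(as.matrix(seqs)))
  # ape decodes unknown/ambiguity codes to their IUPAC letters; restrict to
  # the supported alphabet, mapping every other ambiguity code to N.
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  locus_alignment(mat, locus_id = locus_id, gene_model = gene_model,
                  region = region)
}

#' Read a single outgroup sequence from FASTA
#'
#' @param path FASTA file whose first record is the aligned outgroup.
#' @param L Expected alignment length (checked if non-NULL).
#' @return Character vector of allele codes.
#' @export
read_outgroup <- function(path, L = NULL) {
  if (!file.exists(path) || file.size(path) == 0)
    stop(sprintf("no records in '%s'", path))
  seqs <- ape::read.FASTA(path, type = "DNA")
  if (length(seqs) == 0) stop(sprintf("no records in '%s'", path))
  og <- toupper(as.character(seqs)[[1]])
  og[!(og %in% c("A", "C", "G", "T", "-"))] <- "N"
  if (!is.null(L) && length(og) != L)
    stop(sprintf("outgroup length %d does not match alignment length %d",
                 length(og), L))
  og
}

#' Assign haplotypes to population strata
#'
#' Joins the haplotype ids of an alignment (formatted `<sample_id>/1`,
#' `<sample_id>/2`, or a bare sample id) against a sample metadata table and
#' returns the resulting partition.  Haplotypes whose sample carries an
#' `NA`/empty stratum are dropped (and reported); haplotypes with no metadata
#' row at all are an error.
#'
#' @param aln A [locus_alignment()].
#' @param metadata Data.frame with columns `sample_id` and `stratum`
#'   (additional columns such as `karyotype` and `year` are carried along).
#' @param strata Optional character vector restricting the admissible stratum
#'   labels; any other non-missing label is an error.
#' @return A `population_partition`: list with `stratum` (named character
#'   vector keyed by haplotype id), `counts` (per-stratum chromosome counts)
#'   and `dropped` (ids excluded for lack of a stratum).
#' @export
attach_metadata <- function(aln, metadata, strata = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  md <- as.data.frame(metadata)
  if (!all(c("sample_id", "stratum") %in% names(md)))
    stop("metadata needs columns sample_id and stratum")
  if (anyDuplicated(md$sample_id))
    stop(sprintf("duplicate sample row for '%s'",
                 md$sample_id[duplicated(md$sample_id)][1]))
  ids <- rownames(aln$mat)
  samp <- sub("/[12]$", "", ids)
  hit <- match(samp, md$sample_id)
  if (anyNA(hit))
    stop(sprintf("haplotype '%s' has no metadata row", ids[which(is.na(hit))[1]]))
  stratum <- as.character(md$stratum[hit])
  names(stratum) <- ids
  keep <- !is.na(stratum) & nzchar(stratum)
  if (!is.null(strata)) {
    unknown <- setdiff(unique(stratum[keep]), strata)
    if (length(unknown))
      stop(sprintf("unknown stratum label '%s'", unknown[1]))
  }
  dropped <- ids[!keep]
  if (length(dropped))
    message(sprintf("attach_metadata: dropped %d haplotype(s) with no stratum (%s%s)",
                    length(dropped), paste(utils::head(dropped, 3), collapse = ", "),
                    if (length(dropped) > 3) ", ..." else ""))
  stratum <- stratum[keep]
  structure(list(stratum = stratum,
                 counts = table(stratum),
                 dropped = dropped),
            class = "population_partition")
}

#' Classify alignment columns by functional class
#'
#' Columns outside exons are `noncoding`.  Exon columns are judged codon by
#' codon against the designated reference haplotype: a biallelic substitution
#' whose two codons encode the same amino acid is `synonymous`, a different
#' amino acid `nonsynonymous`.  Columns falling in codons that contain
#' missing data in the reference, carry more than two alleles, or are
#' truncated at the fragment edge are `excluded`.  Monomorphic exon columns
#' are classified by degeneracy of the reference codon position: synonymous
#' only if every possible single-base change there is synonymous (i.e. a
#' fourfold-degenerate site).
#'
#' @param aln A [locus_alignment()] with a gene model.
#' @param reference Haplotype id or row index used as the reference frame.
#' @return Character vector of length `L` with values `"synonymous"`,
#'   `"nonsynonymous"`, `"noncoding"`, `"excluded"`.
#' @export
classify_sites <- function(aln, reference = 1L) {
  stopifnot(inherits(aln, "locus_alignment"))
  gm <- aln$gene_model
  cls <- rep("noncoding", aln$L)
  if (is.null(gm) || nrow(gm) == 0) return(cls)
  if (is.character(reference)) reference <- match(reference, rownames(aln$mat))
  if (is.na(reference) || reference < 1 || reference > aln$n)
    stop("reference haplotype not found")
  ref <- aln$mat[reference, ]

  # Concatenate exon columns into a CDS; the first exon's frame anchors the
  # reading frame, later exons must continue it.
  cds_cols <- integer(0)
  off <- 0L
  for (i in seq_len(nrow(gm))) {
    cols <- seq.int(gm$exon_start[i] + 1L, gm$exon_end[i])  # 1-based
    if (i == 1L) {
      off <- gm$frame[1]
    } else {
      expected <- (off + length(cds_cols)) %% 3L
      if (gm$frame[i] != expected)
        stop(sprintf("model error: exon %d declares frame %d, expected %d",
                     i, gm$frame[i], expected))
    }
    cds_cols <- c(cds_cols, cols)
  }
  if (any(ref[cds_cols] == "-"))
    stop("reference haplotype has gaps inside exons")
  cls[cds_cols] <- "excluded"  # default for partial codons at the edges

  # Codon phase of each CDS position: first complete codon starts where the
  # phase is 0.  'off' bases at the start belong to a truncated codon.
  phase <- (seq_along(cds_cols) - 1L + off) %% 3L
  starts <- which(phase == 0L)
  starts <- starts[starts + 2L <= length(cds_cols)]
  for (s in starts) {
    cod_cols <- cds_cols[s:(s + 2L)]
    ref_cod <- ref[cod_cols]
    if (any(ref_cod %in% .MISSING_CODES)) next  # stays excluded
    codon_bad <- FALSE
    pos_cls <- character(3)
    for (k in 1:3) {
      col <- cod_cols[k]
      obs <- aln$mat[, col]
      obs <- obs[!(obs %in% .MISSING_CODES)]
      alleles <- unique(obs)
      if (length(alleles) > 2) { codon_bad <- TRUE; break }
      if (length(alleles) == 2) {
        aa <- character(2)
        for (j in 1:2) {
          cod <- ref_cod; cod[k] <- alleles[j]
          aa[j] <- .translate_codon(cod)
        }
        pos_cls[k] <- if (aa[1] == aa[2]) "synonymous" else "nonsynonymous"
      } else {
        # monomorphic: degeneracy of the reference codon at this position
        ref_aa <- .translate_codon(ref_cod)
        alt <- setdiff(c("A", "C", "G", "T"), ref_cod[k])
        syn_all <- all(vapply(alt, function(b) {
          cod <- ref_cod; cod[k] <- b
          identical(.translate_codon(cod), ref_aa)
        }, logical(1)))
        pos_cls[k] <- if (syn_all) "synonymous" else "nonsynonymous"
      }
    }
    if (!codon_bad) cls[cod_cols] <- pos_cls
  }
  cls
}

#' Polarize segregating alleles against an outgroup sequence
#'
#' At each biallelic column the allele matching the outgroup is called
#' ancestral and the other derived; columns where the outgroup matches
#' neither allele, is missing, or where more than two alleles segregate are
#' `unpolarizable`.  Columns monomorphic in the sample but different from the
#' outgroup are recorded as `fixed_diff` (used for divergence and HKA).
#'
#' @param aln A [locus_alignment()].
#' @param outgroup Character vector of outgroup allele codes, length `L`.
#' @return Data.frame with one row per column: `status` (`"monomorphic"`,
#'   `"polarized"`, `"unpolarizable"`, `"fixed_diff"`), `ancestral`,
#'   `derived`, `derived_count` (over non-missing entries) and
#'   `n_called` (non-missing entries).
#' @export
polarize_sites <- function(aln, outgroup) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(outgroup) != aln$L)
    stop(sprintf("outgroup length %d does not match alignment length %d",
                 length(outgroup), aln$L))
  outgroup <- toupper(outgroup)
  L <- aln$L
  status <- character(L); anc <- der <- rep(NA_character_, L)
  dcount <- integer(L); ncalled <- integer(L)
  for (j in seq_len(L)) {
    obs <- aln$mat[, j]
    obs <- obs[!(obs %in% .MISSING_CODES)]
    ncalled[j] <- length(obs)
    tab <- table(obs)
    alleles <- names(tab)
    og <- outgroup[j]
    og_ok <- og %in% c("A", "C", "G", "T")
    if (length(alleles) <= 1) {
      if (length(alleles) == 1 && og_ok && og != alleles) {
        status[j] <- "fixed_diff"
        anc[j] <- og; der[j] <- alleles
        dcount[j] <- length(obs)
      } else {
        status[j] <- "monomorphic"
      }
    } else if (length(alleles) == 2 && og_ok && og %in% alleles) {
      status[j] <- "polarized"
      anc[j] <- og
      der[j] <- setdiff(alleles, og)
      dcount[j] <- as.integer(tab[der[j]])
    } else {
      status[j] <- "unpolarizable"
    }
  }
  data.frame(status = status, ancestral = anc, derived = der,
             derived_count = dcount, n_called = ncalled)
}

#' Restrict an alignment to silent (synonymous + noncoding) columns
#'
#' @param aln A [locus_alignment()].
#' @param site_class Output of [classify_sites()] (or any per-column class
#'   vector).
#' @return A [locus_alignment()] containing only the silent columns, with an
#'   attribute `col_map` giving, for each retained column, its (1-based)
#'   index in the original alignment.  The gene model is dropped.
#' @export
silent_subalignment <- function(aln, site_class) {
  stopifnot(inherits(aln, "locus_alignment"), length(site_class) == aln$L)
  keep <- which(site_class %in% c("synonymous", "noncoding"))
  sub <- locus_alignment(aln$mat[, keep, drop = FALSE],
                         locus_id = aln$locus_id, gene_model = NULL,
                         region = aln$region)
  attr(sub, "col_map") <- keep
  sub
}
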
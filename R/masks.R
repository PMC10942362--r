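# Controlled consequence vocabulary and qualifying-variant masks.

#' Consequence vocabulary
#'
#' The fixed, controlled list of variant consequence classes used
#' throughout the package. Annotation input in common annotator dialects
#' (VEP / SnpEff style strings such as `"missense_variant"` or
#' `"stop_gained"`) is normalised onto this vocabulary by
#' [normalize_consequence()]; anything unrecognised maps to `"other"`.
#'
#' @return character vector of the canonical consequence labels.
#' @export
consequence_vocabulary <- function() {
  c("missense", "nonsense", "stop_lost", "start_lost",
    "splice_donor", "splice_acceptor", "splice_region",
    "frameshift", "inframe_ins", "inframe_del", "synonymous", "other")
}

# annotator-string -> canonical label; matching is case-insensitive
consequence_synonyms <- c(
  "missense"                 = "missense",
  "missense_variant"         = "missense",
  "nonsynonymous_snv"        = "missense",
  "nonsense"                 = "nonsense",
  "stop_gained"              = "nonsense",
  "stop-gained"              = "nonsense",
  "stopgain"                 = "nonsense",
  "stop_lost"                = "stop_lost",
  "stop-lost"                = "stop_lost",
  "stoploss"                 = "stop_lost",
  "start_lost"               = "start_lost",
  "start-lost"               = "start_lost",
  "startloss"                = "start_lost",
  "initiator_codon_variant"  = "start_lost",
  "splice_donor"             = "splice_donor",
  "splice_donor_variant"     = "splice_donor",
  "splice-donor"             = "splice_donor",
  "splice_acceptor"          = "splice_acceptor",
  "splice_acceptor_variant"  = "splice_acceptor",
  "splice-acceptor"          = "splice_acceptor",
  "splice_region"            = "splice_region",
  "splice_region_variant"    = "splice_region",
  "splice-region"            = "splice_region",
  "frameshift"               = "frameshift",
  "frameshift_variant"       = "frameshift",
  "inframe_ins"              = "inframe_ins",
  "inframe_insertion"        = "inframe_ins",
  "in-frame_insertion"       = "inframe_ins",
  "inframe_del"              = "inframe_del",
  "inframe_deletion"         = "inframe_del",
  "in-frame_deletion"        = "inframe_del",
  "synonymous"               = "synonymous",
  "synonymous_variant"       = "synonymous",
  "coding-synonymous"        = "synonymous",
  "other"                    = "other")

#' Normalise annotator consequence strings
#'
#' @param x character vector of consequence strings in any supported
#'   annotator dialect.
#' @param warn warn when unknown strings are mapped to `"other"`.
#' @return character vector over [consequence_vocabulary()].
#' @export
normalize_consequence <- function(x, warn = TRUE) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(consequence_synonyms[key])
  unknown <- is.na(out) & !is.na(key) & nzchar(key)
  if (any(unknown) && warn)
    warning("unknown consequence string(s) mapped to 'other': ",
            paste(unique(key[unknown]), collapse = ", "))
  out[is.na(out)] <- "other"
  out
}

#' Define a qualifying-variant mask
#'
#' A mask is a named rule deciding which variants enter a burden or trend
#' test: a set of consequence classes, a MAF ceiling, and (optionally) an
#' in-silico deleteriousness requirement applied to missense variants
#' (PolyPhen2 "P"/"D" or SIFT "deleterious"); loss-of-function classes
#' bypass the missense predicate.
#'
#' @param name mask label.
#' @param consequences subset of [consequence_vocabulary()].
#' @param maf_max MAF ceiling in (0, 0.5]; variants qualify at MAF strictly
#'   below this value.
#' @param require_deleterious if `TRUE`, missense variants additionally
#'   need a damaging PolyPhen2/SIFT call.
#' @return a `mask_spec` object.
#' @export
mask_spec <- function(name, consequences, maf_max = 0.01,
                      require_deleterious = FALSE) {
  consequences <- unique(as.character(consequences))
  bad <- setdiff(consequences, consequence_vocabulary())
  if (length(bad)) stop("unknown consequence class(es): ",
                        paste(bad, collapse = ", "))
  if (length(consequences) == 0L) stop("mask needs at least one consequence")
  if (!(maf_max > 0 && maf_max <= 0.5)) stop("maf_max must be in (0, 0.5]")
  structure(list(name = name, consequences = consequences,
                 maf_max = maf_max,
                 require_deleterious = isTRUE(require_deleterious)),
            class = "mask_spec")
}

#' Standard masks
#'
#' The three mask families used in rare-variant panel analyses:
#' * `nonsynonymous` - missense, nonsense (stop gained), stop/start lost and
#'   the three splice classes (donor, acceptor, region);
#' * `synonymous` - the internal negative-control channel;
#' * `missense` - missense only;
#' * `damaging` - missense restricted to PolyPhen2 "P"/"D" or SIFT
#'   "deleterious" calls, plus all splice, stop-gained/lost, start-lost,
#'   frameshift and in-frame indel classes.
#'
#' @param maf_max MAF ceiling shared by all masks (default 0.01).
#' @return named list of [mask_spec()] objects.
#' @export
default_masks <- function(maf_max = 0.01) {
  splice <- c("splice_donor", "splice_acceptor", "splice_region")
  list(
    nonsynonymous = mask_spec(
      "nonsynonymous",
      c("missense", "nonsense", "stop_lost", "start_lost", splice),
      maf_max = maf_max),
    synonymous = mask_spec("synonymous", "synonymous", maf_max = maf_max),
    missense = mask_spec("missense", "missense", maf_max = maf_max),
    damaging = mask_spec(
      "damaging",
      c("missense", "nonsense", "stop_lost", "start_lost", splice,
        "frameshift", "inframe_ins", "inframe_del"),
      maf_max = maf_max, require_deleterious = TRUE))
}

#' Select the qualifying variants of a mask
#'
#' A variant qualifies iff its consequence is in the mask, its cohort MAF
#' is strictly below the mask ceiling, and -- for masks with
#' `require_deleterious` -- a missense variant carries a damaging
#' PolyPhen2 ("P"/"D") or SIFT ("deleterious") call. Results are returned
#' in deterministic (chrom, pos, alt) order.
#'
#' @param dataset an annotated [cohort_dataset()].
#' @param mask a [mask_spec()].
#' @param gene_filter optional [gene_set()]; restrict to these genes.
#' @param maf_group group on which MAF is computed (see [compute_maf()]).
#' @param maf optional precomputed per-variant MAF vector (named by vid);
#'   avoids recomputing it in tight loops.
#' @return character vector of qualifying variant ids (possibly empty).
#' @export
select_mask_variants <- function(dataset, mask, gene_filter = NULL,
                                 maf_group = "combined", maf = NULL) {
  if (is.null(dataset$annotations))
    stop("dataset has no annotations; attach them before masking")
  ann <- dataset$annotations
  keep <- ann$consequence %in% mask$consequences
  if (mask$require_deleterious) {
    damaging <- (!is.na(ann$polyphen) & ann$polyphen %in% c("P", "D")) |
      (!is.na(ann$sift) & ann$sift == "deleterious")
    keep <- keep & (ann$consequence != "missense" | damaging)
  }
  if (!is.null(gene_filter)) keep <- keep & ann$gene %in% gene_filter$genes
  vids <- unique(ann$vid[keep])
  if (is.null(maf)) maf <- compute_maf(dataset, group = maf_group)
  vids <- vids[vids %in% names(maf)[!is.na(maf) & maf < mask$maf_max]]
  v <- dataset$variants[match(vids, dataset$variants$vid), , drop = FALSE]
  vids[order(v$chrom, v$pos, v$alt)]
}
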
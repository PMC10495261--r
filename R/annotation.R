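#' Assign peaks to genomic region categories
#'
#' Each peak is assigned, by its midpoint, to exactly one of promoter, tts,
#' exon, intron or intergenic, in that priority order (a midpoint inside
#' both a promoter window and another gene's exon is a promoter peak).
#' Windows are strand-aware and measured in transcription direction:
#' promoter covers `promoter_up` bp upstream through `promoter_down` bp
#' downstream of the TSS, and the TTS window analogously around the TTS.
#' Among genes of equal priority the gene whose TSS is nearest to the
#' midpoint wins. Defaults mirror common annotator practice
#' (promoter -1000/+100, TTS -100/+1000).
#'
#' @param peaks A `GRanges`.
#' @param genes Gene models from [read_gtf_genes()].
#' @param promoter_up,promoter_down Promoter window, bp up/downstream of the
#'   TSS in transcription direction.
#' @param tts_up,tts_down TTS window, bp up/downstream of the TTS.
#' @return A data.frame along `peaks` with columns `category` (factor with
#'   levels promoter, tts, exon, intron, intergenic) and `gene_id`
#'   (`NA` iff intergenic).
#' @export
assign_region <- function(peaks, genes, promoter_up = 1000L,
                          promoter_down = 100L, tts_up = 100L,
                          tts_down = 1000L) {
  mid0 <- floor((start(peaks) - 1L + end(peaks)) / 2)
  mids <- GRanges(seqnames(peaks), IRanges(mid0 + 1L, width = 1L))

  plus <- as.character(strand(genes)) == "+"
  win_gr <- function(s0, e0) {
    s0 <- pmax(s0, 0)
    GRanges(seqnames(genes), IRanges(s0 + 1L, pmax(e0, s0 + 1L)))
  }
  prom <- win_gr(ifelse(plus, genes$tss - promoter_up, genes$tss - promoter_down),
                 ifelse(plus, genes$tss + promoter_down, genes$tss + promoter_up))
  ttsw <- win_gr(ifelse(plus, genes$tts - tts_up, genes$tts - tts_down),
                 ifelse(plus, genes$tts + tts_down, genes$tts + tts_up))
  exon_gr <- unlist(genes$exons, use.names = FALSE)
  exon_gene <- rep(seq_along(genes), lengths(genes$exons))

  category <- rep(NA_character_, length(peaks))
  gene_idx <- rep(NA_integer_, length(peaks))

  claim <- function(targets, target_gene) {
    hits <- findOverlaps(mids, targets, ignore.strand = TRUE)
    q <- queryHits(hits)
    open <- is.na(category[q])
    q <- q[open]
    g <- target_gene[subjectHits(hits)][open]
    if (length(q) == 0L) return(invisible(NULL))
    # nearest-TSS tie-break among candidate genes for one midpoint
    d <- abs(mid0[q] - genes$tss[g])
    ord <- order(q, d, genes$gene_id[g])
    q <- q[ord]; g <- g[ord]
    first <- !duplicated(q)
    category[q[first]] <<- cat_name
    gene_idx[q[first]] <<- g[first]
    invisible(NULL)
  }
  cat_name <- "promoter"; claim(prom, seq_along(genes))
  cat_name <- "tts";      claim(ttsw, seq_along(genes))
  cat_name <- "exon";     claim(exon_gr, exon_gene)
  cat_name <- "intron";   claim(granges(genes), seq_along(genes))
  category[is.na(category)] <- "intergenic"

  data.frame(
    category = factor(category,
                      levels = c("promoter", "tts", "exon", "intron", "intergenic")),
    gene_id = ifelse(is.na(gene_idx), NA_character_, genes$gene_id[gene_idx]),
    stringsAsFactors = FALSE)
}

#' Summarize the genomic-region distribution of peaks
#'
#' Counts and fractions of peaks per region category ([assign_region()]),
#' optionally stratified by a per-peak group label (e.g. m6A(+) versus
#' m6A(-) peaks). Fractions sum to 1 within each stratum; empty strata are
#' dropped with a warning.
#'
#' @param peaks A non-empty `GRanges`.
#' @param genes Gene models from [read_gtf_genes()].
#' @param strata Optional vector of group labels along `peaks`.
#' @param ... Window parameters passed to [assign_region()].
#' @return A data.frame with columns `stratum`, `category`, `count`,
#'   `fraction`.
#' @export
region_distribution <- function(peaks, genes, strata = NULL, ...) {
  if (length(peaks) == 0L) stop("peaks is empty")
  if (is.null(strata)) strata <- rep("all", length(peaks))
  if (length(strata) != length(peaks)) stop("strata must match peaks in length")
  lv <- if (is.factor(strata)) levels(strata) else unique(as.character(strata))
  strata <- as.character(strata)
  asg <- assign_region(peaks, genes, ...)
  out <- do.call(rbind, lapply(lv, function(s) {
    sel <- strata == s
    if (!any(sel)) {
      warning("stratum '", s, "' is empty; omitted")
      return(NULL)
    }
    tab <- table(asg$category[sel])
    data.frame(stratum = s, category = factor(names(tab), levels = names(tab)),
               count = as.integer(tab),
               fraction = as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
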
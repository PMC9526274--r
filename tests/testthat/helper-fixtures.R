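# Fixtures are built in code, deterministically, and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# ---- micro fixture: two hand-built genes with known codons ----------------
#
# Gene GP (plus strand):  exon1 91-130 (UTR 91-100, CDS 101-130 = codons
# 1-10), intron 131-230, exon2 231-280 (CDS 231-260 = codons 11-20, UTR
# 261-280). Gene GQ (minus strand): exon 341-420, CDS 351-410 (20 codons in
# translation order from genomic 410 down to 351).

codons_P <- c("ATG", "GGA", "AAA", "TAC", "CCT", "GAC", "TTT", "CAT", "CGA",
              "GTT", "CTG", "TCA", "GAA", "TGG", "ATC", "AAC", "GGT", "CTC",
              "TAT", "TAA")
codons_Q <- c("ATG", "GGA", "AAA", "TAC", "CCT", "GAC", "TTT", "CAT", "CGA",
              "GTT", "CTG", "TCA", "GAA", "TGG", "ATC", "AAC", "GGT", "CTC",
              "TAT", "TGA")

micro_sequence <- function() {
  filler <- rep(c("A", "C", "G", "T"), length.out = 600)
  s <- filler
  coding_P <- strsplit(paste(codons_P, collapse = ""), "")[[1]]
  s[101:130] <- coding_P[1:30]
  s[231:260] <- coding_P[31:60]
  coding_Q <- paste(codons_Q, collapse = "")
  s[351:410] <- strsplit(vectann::reverse_complement(coding_Q), "")[[1]]
  paste(s, collapse = "")
}

micro_gtf_lines <- function(extra_tx = FALSE) {
  a <- function(g, t, tag = NULL) {
    s <- sprintf('gene_id "%s"; transcript_id "%s";', g, t)
    if (!is.null(tag)) s <- paste0(s, sprintf(' tag "%s";', tag))
    s
  }
  lines <- c(
    sprintf("chrT\ttest\texon\t91\t130\t.\t+\t.\t%s", a("GP", "P.t1")),
    sprintf("chrT\ttest\texon\t231\t280\t.\t+\t.\t%s", a("GP", "P.t1")),
    sprintf("chrT\ttest\tCDS\t101\t130\t.\t+\t0\t%s", a("GP", "P.t1")),
    sprintf("chrT\ttest\tCDS\t231\t260\t.\t+\t0\t%s", a("GP", "P.t1")),
    sprintf("chrT\ttest\texon\t341\t420\t.\t-\t.\t%s", a("GQ", "Q.t1")),
    sprintf("chrT\ttest\tCDS\t351\t410\t.\t-\t0\t%s", a("GQ", "Q.t1"))
  )
  if (extra_tx) {
    lines <- c(lines,
      sprintf("chrT\ttest\texon\t86\t130\t.\t+\t.\t%s", a("GP", "P.t2")),
      sprintf("chrT\ttest\texon\t231\t286\t.\t+\t.\t%s", a("GP", "P.t2")),
      sprintf("chrT\ttest\tCDS\t101\t130\t.\t+\t0\t%s", a("GP", "P.t2")),
      sprintf("chrT\ttest\tCDS\t231\t260\t.\t+\t0\t%s", a("GP", "P.t2")),
      sprintf("chrT\ttest\texon\t91\t130\t.\t+\t.\t%s",
              a("GP", "P.nmd", "nonsense_mediated_decay")),
      sprintf("chrT\ttest\texon\t231\t280\t.\t+\t.\t%s",
              a("GP", "P.nmd", "nonsense_mediated_decay")),
      sprintf("chrT\ttest\tCDS\t101\t130\t.\t+\t0\t%s",
              a("GP", "P.nmd", "nonsense_mediated_decay")),
      sprintf("chrT\ttest\tCDS\t231\t260\t.\t+\t0\t%s",
              a("GP", "P.nmd", "nonsense_mediated_decay"))
    )
  }
  lines
}

build_micro <- function(extra_tx = FALSE) {
  dir <- tempfile("micro")
  dir.create(dir)
  fasta <- file.path(dir, "micro.fa")
  gtf <- file.path(dir, "micro.gtf")
  writeLines(c(">chrT", micro_sequence()), fasta)
  writeLines(micro_gtf_lines(extra_tx), gtf)
  model <- load_gene_annotation(gtf)
  store <- load_genome(fasta)
  ts <- build_transcript_targets(model, l_ext = 10)
  list(dir = dir, fasta = fasta, gtf = gtf, model = model, store = store,
       targets = ts)
}

micro_fixture <- function() fixture("micro", function() build_micro(FALSE))
micro2_fixture <- function() fixture("micro2", function() build_micro(TRUE))

# ---- large fixture: default study conditions (1 Mb, 50 genes, p = 0.25) ---

big_fixture <- function() {
  fixture("big", function() {
    cfg <- sim_config(seed = 101)
    dir <- tempfile("big")
    ref <- simulate_reference(cfg, dir)
    model <- load_gene_annotation(ref$gtf)
    store <- load_genome(ref$fasta)
    ts <- build_transcript_targets(model, l_ext = 10)
    av <- build_annotation_vectors(model, store, ts)
    vt <- simulate_variants(ts, store, cfg)
    vcf <- file.path(dir, "variants.vcf")
    write_vcf(vt, vcf)
    vs <- parse_vcf(vcf)
    list(cfg = cfg, dir = dir, ref = ref, model = model, store = store,
         targets = ts, av = av, variants = vt, vcf = vcf, vs = vs)
  })
}

# a target set built from plain interval specs (exercises the BED reader)
targets_from_spec <- function(regions) {
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s|%s|%s|cds\t0\t%s",
                     regions$chrom, regions$start - 1L, regions$end,
                     regions$element_id, regions$element_id,
                     ifelse(is.na(regions$frame), ".", regions$frame),
                     regions$strand),
             bed)
  read_targets_bed(bed)
}

record_key <- function(r) {
  paste(r$chrom, r$start, r$end, r$type, r$allele, r$element_id,
        vapply(r$terms, paste, character(1), collapse = ","))
}

high_key <- function(r) {
  paste(r$chrom, r$start, r$end, r$type, r$element_id,
        vapply(r$terms, function(tt) {
          paste(intersect(tt, high_impact_terms()), collapse = ",")
        }, character(1)))
}

variant_key <- function(r) paste(r$chrom, r$start, r$end, r$type, r$element_id)
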
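# Shared fixtures, built in code.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal metadata for two families (mother + infant each), three timepoints,
# VLP + TOTAL sources.
toy_metadata <- function(families = c("F01", "F02"),
                         mother_tps = c("P7", "B", "M1"),
                         infant_tps = c("M1", "M3", "M6"),
                         sources = c("VLP", "TOTAL")) {
  rows <- list()
  for (f in families) {
    for (ind in c(sprintf("%s_M", f), sprintf("%s_I1", f))) {
      role <- if (grepl("_M$", ind)) "mother" else "infant"
      tps <- if (role == "mother") mother_tps else infant_tps
      for (tp in tps) for (src in sources) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%s", ind, tp, src),
          individual_id = ind, family_id = f, role = role, timepoint = tp,
          age_days = 0, source = src, library_size = 1e6, dna_conc = 10,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# 20-scaffold annotation fixture with hand-enumerated expected outcomes of
# the curation rule engine (see expected_* below).
curation_fixture <- function() {
  s <- function(id, len, circ = FALSE, vs = FALSE, pvog = 0L, rps = 0L,
                rrna = FALSE, refseq = FALSE, crass = FALSE, nt = FALSE,
                vc, negctrl = FALSE, integ = FALSE, recomb = FALSE,
                ci = FALSE) {
    data.frame(scaffold_id = id, length_bp = len, circular = circ,
               virsorter_positive = vs, pvog_hits = pvog,
               ribosomal_protein_genes = rps, rrna_hit = rrna,
               refseq_viral_hit = refseq, crass_hit = crass, nt_hit = nt,
               vc_id = vc, negctrl_cluster = negctrl,
               checkv_quality = "Low-quality", integrase = integ,
               recombinase = recomb, ci_repressor = ci,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("s01", 5000, circ = TRUE, vc = "VC_X", negctrl = TRUE),     # negctrl drop
    s("s02", 2000, nt = TRUE, vc = "VC_X"),                       # no criterion
    s("s03", 1500, refseq = TRUE, nt = TRUE, vc = "VC_A", integ = TRUE),
    s("s04", 10000, pvog = 3L, vc = "VC_A", recomb = TRUE),       # {2,6}
    s("s05", 1200, vs = TRUE, nt = TRUE, vc = "VC_B",
      recomb = TRUE, ci = TRUE),
    s("s06", 1100, circ = TRUE, nt = TRUE, vc = "VC_B"),
    s("s07", 1500, crass = TRUE, nt = TRUE, vc = "VC_C"),
    s("s08", 3500, vc = "VC_C"),                                  # {6}
    s("s09", 3000, vc = "VC_C"),                                  # 3000 not > 3000
    s("s10", 1200, pvog = 2L, nt = TRUE, vc = "VC_C"),            # 2 pVOGs < 3
    # VC_D condemned by rrna (s11); s12 rescued r1, s13 rescued r3, s14 lost
    s("s11", 5000, circ = TRUE, rrna = TRUE, nt = TRUE, vc = "VC_D"),
    s("s12", 1500, circ = TRUE, pvog = 2L, nt = TRUE, vc = "VC_D"),
    s("s13", 1400, vs = TRUE, nt = TRUE, vc = "VC_D"),
    s("s14", 4000, vc = "VC_D"),
    # VC_E condemned by rule b (s15); s16 rescued r2
    s("s15", 10000, pvog = 1L, rps = 1L, vc = "VC_E"),
    s("s16", 2000, circ = TRUE, vs = TRUE, nt = TRUE, vc = "VC_E"),
    # VC_F condemned by rule c (s17, 4 ribosomal proteins); s18 rescued r1
    s("s17", 20000, vs = TRUE, pvog = 5L, rps = 4L, vc = "VC_F"),
    s("s18", 9000, circ = TRUE, pvog = 3L, nt = TRUE, vc = "VC_F"),
    # VC_G clean: passes whole
    s("s19", 1300, vs = TRUE, nt = TRUE, vc = "VC_G"),
    s("s20", 1050, circ = TRUE, pvog = 1L, nt = TRUE, vc = "VC_G"))
}

expected_retained <- c("s03", "s04", "s05", "s06", "s07", "s08", "s12",
                       "s13", "s16", "s18", "s19", "s20")

expected_criteria <- c(s03 = "1", s04 = "2,6", s05 = "3", s06 = "4",
                       s07 = "5", s08 = "6", s12 = "4", s13 = "3",
                       s16 = "3,4", s18 = "2,4", s19 = "3", s20 = "4")

expected_lifestyle <- c(s03 = "temperate",  # integrase
                        s04 = "virulent",   # recombinase without CI repressor
                        s05 = "temperate",  # recombinase + CI repressor
                        s06 = "virulent", s07 = "virulent", s08 = "virulent",
                        s12 = "virulent", s13 = "virulent", s16 = "virulent",
                        s18 = "virulent", s19 = "virulent", s20 = "virulent")
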
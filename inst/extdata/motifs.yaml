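# CRE motif catalogue (IUPAC patterns).
# CTGTTG / CTGTTA are literal MYB-core variants; the remaining entries
# are PLACE-style consensus defaults shipped as reasonable stand-ins
# where only a motif family, not an exact consensus, is established.
- name: CGCGBOXAT
  pattern: VCGCGB
  source: "CGCG box bound by calmodulin-binding SR/CAMTA transcription factors (PLACE consensus)"
- name: MYBCORE_G
  pattern: CTGTTG
  source: "MYB recognition core, G variant (literal)"
- name: MYBCORE_A
  pattern: CTGTTA
  source: "MYB recognition core, A variant (literal)"
- name: ABRE_like
  pattern: YACGTG
  source: "ABA-responsive element-like ACGT core (PLACE-style consensus default)"
- name: CE3
  pattern: AACGCGTGTC
  source: "ABA-response coupling element 3 (PLACE-style consensus default)"
- name: CBF_site
  pattern: RCCGAC
  source: "CBF/DREB dehydration-responsive element core (PLACE-style consensus default)"
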
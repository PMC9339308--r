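Staging area for externally derived per-codon footprint count tables used by
the per-gene stall-score anchor test. These tables are not shipped: they are
produced from public ribosome profiling datasets (bacterial efp mutants,
mouse liver Trsp knockout, LARP1 knockout cells) after raw-read download,
alignment, and P-site assignment.

Expected files (TSV: transcript_id, codon_index, count):
  cysQ_control.tsv    cysQ_mutant.tsv
  Sephs2_control.tsv  Sephs2_mutant.tsv
  Rpl13_control.tsv   Rpl13_mutant.tsv

Without these files the anchor test fails by design rather than silently
passing.
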
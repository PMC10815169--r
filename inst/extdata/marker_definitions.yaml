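# Marker definitions for the three cloned plant-height loci.
#
# Primers and product lengths follow the published assay; the reference
# amplicons are SYNTHETIC stand-ins (fixed-seed random sequences
# bracketed by the primers, carrying each allele-defining feature at the
# offset given here), since full amplicon sequences are not published.
# site_offset / dup_start are 1-based coordinates in the recessive
# reference amplicon; published_position keeps the published coordinate
# label as metadata only (it is not resolvable inside the amplicon).
reference_fasta: synthetic_reference_amplicons.fasta
markers:
  - locus: DW1
    kind: SNP
    primer_fwd: TGGCGGTCCAACGTCTAAT
    primer_rev: CCTGAAGTATGGCGTGTCT
    reference_record: dw1_recessive_amplicon
    site_offset: 214            # recessive base A; A->T is the dominant Dw1 mutation
    dominant_base: T
    expected_length_recessive: 427
    expected_length_dominant: 427
    published_position: "1350"
  - locus: DW2
    kind: DELETION
    primer_fwd: CAGTTCAAATCAACGAGGAG
    primer_rev: TCCGTCGTGAAATGAGAATA
    reference_record: dw2_recessive_amplicon
    site_offset: 548            # GA present after this base in the dominant allele
    indel_seq: GA
    expected_length_recessive: 995
    expected_length_dominant: 997
    published_position: "549"
  - locus: DW3
    kind: INSERTION
    primer_fwd: CGTCATCGTCCAGAACTCGG
    primer_rev: GACCCTTGCTCCACCACCTT
    reference_record: dw3_recessive_amplicon
    dup_start: 200              # block [200, 1081] tandem-duplicated in Dw3
    dup_length: 882
    expected_length_recessive: 1263
    expected_length_dominant: 2145
    published_position: "fifth exon, 882 bp direct duplication"
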
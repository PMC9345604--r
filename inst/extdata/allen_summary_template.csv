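# Template grouping table for load_ontology(grouping=) in real-atlas mode.
# Columns: leaf_id (Allen structure id), region69 (reporting region),
# summary25 (summary category). The vestibular grouping below follows the
# convention of collapsing the spinal, medial, lateral and superior
# vestibular nuclei into a single category; the remaining rows are
# EDITABLE placeholders to be completed for the atlas version in use.
leaf_id,region69,summary25
209,SPIV,Vestibular
202,MV,Vestibular
72,LAV,Vestibular
217,SUV,Vestibular
1048,GRN,Gigantocellular
307,MARN,Gigantocellular
938,PGRNl,Gigantocellular
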
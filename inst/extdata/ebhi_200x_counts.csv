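category,images,binary_label
Normal,61,benign
Polyp,254,benign
Low-grade IN,603,benign
High-grade IN,130,malignant
Adenocarcinoma,790,malignant
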
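file	md5
curation_variants.tsv	c499b6bd7c535ac1c0a64d3bd9b8380c
toy_grid.tsv	a46203de6ed2b150dca030c3653615ed
mini_features.tsv	17856f5a53527a291b58eed52ab6c9fe
mini_truth.tsv	80802a1df73be08364cff51bdf71a319
mini_sites.tsv	1216ad4150064df7b3368a382c53df88
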
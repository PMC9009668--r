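city	vendor_type	n	pct_mislabeled
Mazatlan	fish_market	33	33.3
Mazatlan	grocery_store	24	8.3
Mazatlan	restaurant	63	38.0
Mexico City	fish_market	47	44.6
Mexico City	grocery_store	33	24.2
Mexico City	restaurant	70	31.4
Cancun	fish_market	27	25.9
Cancun	grocery_store	21	14.2
Cancun	restaurant	58	31.0
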
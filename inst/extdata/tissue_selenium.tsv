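tissue	diet	mean	sem	n	unit
liver	0Se	0.1065	0.0143	3	ug/g
liver	0.1Se	1.0830	0.0240	3	ug/g
lung	0Se	0.1096	0.0129	3	ug/g
lung	0.1Se	0.3163	0.0149	3	ug/g
plasma	0Se	0.0559	0.0090	3	ug/mL
plasma	0.1Se	0.3510	0.0078	3	ug/mL
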
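label	total_cells	transduction_fraction	barcodes_recovered	n_mice
L4951_10000_diluted	100000	0.10	662	3
L4951_10000	100000	0.10	784	3
L4951_1000	10000	0.10	155	3
L4951_100	1000	0.10	41	3
L4967_5000	100000	0.05	798	2
P929_1500	150000	0.01	52	2
L707_5000	100000	0.05	705	2
L707_500	10000	0.05	56	2
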
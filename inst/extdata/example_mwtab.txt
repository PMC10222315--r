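#METABOLOMICS WORKBENCH synthetic_example
MS_METABOLITE_DATA_START
Samples	case01	case02	case03	ctrl01	ctrl02	ctrl03
Factors	Group:CRC	Group:CRC	Group:CRC	Group:HC	Group:HC	Group:HC
succinic_acid	310.2	275.9	401.4	150.3	171.8	129.9
butyric_acid	120.5	98.2		505.1	610.7	480.2
leucine	8.4	9.1	7.7	4.9	5.2	4.4
MS_METABOLITE_DATA_END
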
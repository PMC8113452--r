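label	type	case_mean	case_sd	case_n	control_mean	control_sd	control_n	case_yes	case_no	control_yes	control_no
Age	continuous	53.8	13.2	89	50.5	14.5	84	NA	NA	NA	NA
BMI	continuous	21.2	3.1	89	24.5	3.6	84	NA	NA	NA	NA
Gender (female)	categorical2	NA	NA	NA	NA	NA	NA	38	51	36	48
Smoking (smoker)	categorical2	NA	NA	NA	NA	NA	NA	39	50	15	69
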
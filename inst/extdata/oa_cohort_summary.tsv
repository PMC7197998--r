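variable	group	mean	sd	n
age	case	47.2	12.4	92
age	control	40.9	12.0	147
bmi	case	29.0	4.19	92
bmi	control	24.8	4.38	147
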
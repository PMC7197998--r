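sex	case	control
female	80	105
male	12	42
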
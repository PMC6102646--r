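{"R_b":41.1445876556413,"Z":52.0306880899983,"L":10.48132072598,"H":6.66273039870026,"e":0.650681869591188,"psi0":-1.30456419338608}
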
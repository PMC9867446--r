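>CBS1 synthetic CBS reference segment
DKRQSKNTDEPTNEPQSDTRSHQTNNGGHDRSTKQRSKGPNQKPQDRNNS
>CBS2 synthetic CBS reference segment
DQQGHRDRQDRQQKEQKETGSPKSKNESSGRGTEPKTKEHTREQGEQKSQ
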
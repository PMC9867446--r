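>CLC_SCAFFOLD_SYNTH
PPEQGDRYSTLRPEDHHSDNPKAHSDTPDQRQTGSQSKPNTDSHDHQGHNTTTRSRGKED
GARNQKEQGESKKDKRSTDSNKTGRNESSEGSKPPRTDRNGKKTHHRRNSNQRDNNSTNQ
VVIIFVAMLFAIIAAIFLFILRSGPGIPENDTELVFFFLALLFVFVIFLLLIAINQSHKE
QDGKRDILILVVLLFVVVVLFIFFAAVHPGKEGPSVHAELFFAFLLLFLLLLILFFAIAV
STKNEEKKERTSLVMVLLIIVLVFIVIAVLIMVSDPDNGSLFDDNFVNLLVLVLMFLAIV
LILLIVDSPSTKSDGPTQLLVAVLLILFLIIIFLVAILAEDKQGSDTGGTELAALFVLAV
VVVVVLLMVLVLEGPQTSQSSGEKVLAFVVVLFILLVVLVAAVLVTQTSPHDDNPKRVLM
VLLALIAMVVLLIAVFFFENQKPDPESSHDALLVIVIVFLVLFVLLMVFAVQTDKREKSK
KTQILLFVIMVVIILMIIIAVLLVSPNKPEKREEDTKETNQPQKDKRQSKNTDEPTNEPQ
SDTRSHQTNNGGHDRSTKQRSKGPNQKPQDRNNSKGSSNNEPGGKDAADREQDADQQGHR
DRQDRQQKEQKETGSPKSKNESSGRGTEPKTKEHTREQGEQKSQDGDTHPKHQGDDKSDE
RPTDEESLLEDRSTSKKEETDQRH
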
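>HOM_A_SYNTH synthetic homolog
PPEQGDRYSTLRPEDHHSDNPKANSDTPDQKQTGSQSKPNTDKHDHQGHNRTTRDRGKED
GARNQKEQGENKKDKRSTDSSKTGRNESPEGSKKPRTDRNGKQSHARRNSGKRDNQSTNQ
VVIIFVLMLFAIIAAIFLFILRSGPGIPENDTELVFFFIALLFVFVIFLLLIAINQSHSE
QDGKRDILILVVLLFVFVVLFIVFAAVHPGKEGPSVHAELFFAFFLLFLLLLIFFFAIIV
STKNEEKKERTSLVMVLLIIVLVFLVIAVLIMVSDPDNGSLFDDNFVSLLVLVVMFLVIV
LILLIVTSPSTDSDGPTQLLVAVLLILFLIIIFLVAIAAEDKQGSDTGGTEVAMLFVLAV
VVVVVIIMVLFLEGPQTSQSSGEKVLFFVVFLFILLVVLVAAVLVTQTSPHDDNPKRVLM
VLLALIAMVVLLIAVFFFENTKPDPESSHDALLVIVIVFLVLFVLLMVFAVQTDKREKSK
KNQILLFVIMVVIILMIIIAVLLVSPNKREKTEEQTKETTQPQKDKRQSKNTDEPTNEPQ
SDTRSHQTNNGGHDRSTKQRSKGPNQKPQDRNNSKGSSNNEPGGKDAADREQDADQQGHR
DRQDRQQKEQKETGSPKSKNESSGRGTEPKTKEHTREQGEQKSQDGDTHKKHQGDDKSDE
RPDDEESLLEDRTTSKKEETDQRH
>HOM_B_SYNTH synthetic homolog
PPEQRDRYSTLRPEDHHSDNPKAHSDTPDQTQTGSQTKPNSDSHDHQGQNDTTRSRGRED
GARNQEEQEESKKDKRSTDSNDTGRNESQEGSKPRRTDENGKKTHHRRTSNQRDNQSTNQ
VFIIFVAMLFAIIAAIFLFILRSGPGIPENDTEMVFFFLALLLVFVIFLLLIFISQSHKE
TDGTRDILILVVLLVVVLVLFIFLAFVHPGKEGPSVHAPLFIAVILLFLLLLILFFAIAV
STKNEEKKKTTHIVMVLIIIVLVFIVFFVLIMVSDPDNGSLFDDNLVSLLVLVLMFLAIV
LILLIVDSPSTKSDQPTQLLVAVLLILMLIILVLVAILAEDKRGSDTSGTELAALFVLAL
VVVVVVVMILVLEGRQTSQSSGENVLLFIVVLFIFLVVLAAFVLVTQSSPHDDNPKRFLM
VLLAMVAMVFLLIAVFFFENQKPDPESSKDALLIIVIVFLVLFVLLMVFAVDTDKREKQK
KSQILLFVIMVVIILMIIIAVILVSPNKPEKREEKTKETNQPQKDKRQSKNTDEPTNEPQ
SDTRSHQTNNGGHDRSTKQRSKGPNQKPQDRNNSKGSSHNEPGNKDAADREQDADQQGHR
DRQDRQQKEQKETGSPKSKNESSGRGTEPKTKEHTREQGEQKSQDGTKHPHTQGTDDSDE
RPTDEESLLEDGSTSKKEETDQRH
>HOM_C_SYNTH synthetic homolog
PQEQSSRYSTLRNEDHHSDSRKAHSDTPDQRQTGSQSTPNTDSDDHQGHQQTTRSRGPED
GARNQKEQGESKKDKRSTDSKKTGRNESSEGSKPPRTRRNGKKTHHEDNSNQRDNNSTNQ
VVIIFVAMLFLIIAAIFLFILRSGSGIPEAHTELVFFFLVLLFVFVIFLLLIAINQSHRE
QDGKRNILILVVLLFVVFVLFIFLAAVEPGKEGPSVHAELFFAFLLVFLLLLILFFAIAV
STKNEEKDERTSLVMVLLIIVAVFIIIAVLAMVSDPDNGSLFDDNFVTLLVLAFMFLAIV
LILLIVDSKSTKKDGPTELLVAVLLILFLIIIFLVAILAEDSQGDDTGGKELMALFVLAV
VVVAVLLMVLLLEGPQTSQSSGEKVLAFVVVLFLLLLVLVLAVLVTQTSPHRDNSKRLLM
VLLFLIAMVVLVIAVFFFENQKPDPQSSHDMLLVIVIVFLVFFFLLMVFAVQTDKREKSK
KQQILLFVIMVVIFLMIMIAVLLVSPNKPEKREEDTKRENQPQKDKRQSKNTDEPTNEPQ
SDTRSHQTNNGGHDRSTKQRSKGPNQKPQDRNNSKGSSNNEPGGKDTADREQDADQQGHR
DRQDRQQKEQKETGSPKSKNESSGRGTEPKTKEHTREQGEQKSQDGHTHPKHQGDDTSDE
RPSDEESLLEDRSTSKKEETDQRH
>HOM_D_SYNTH synthetic homolog
PPEQGDRYSTLDPEDHHQDDPHTHSDTSDPRQTKSQSKPNDDPHADQKHKDTTRSRPKED
KARNQKGQNESKKDKPDTDSNTGGRSESKEGSKPDRDERNGKKTHHRRGSNTRNNNSNSQ
LVIIFVAMLFAILLAIFLFLLDSGSGIPENDEELVFFILALLLVFVIVLLLVAVNQSHKE
QKGKRHILILFVLIIVVVVLLIIFAFVHPGKEGPSVHAELFAAFFLVILLLLILIAAIAV
QTKNEEKKERDKLVMVLLIFVLVIFFIAVLIMVGGPDNGSLFNDNLVFLLVLVIMFLAIV
LIALIMDGSETKDDGPTHFLVMVLLILFIILIFFVAIVAEDKDGSPTTGTELMLIFVLAV
VVVVVLLMLLVLEGPHTSRSSGEKVFIFVVVLFILLVVLVAALLVTQTSPRRDHPRRVLF
LLVAAILMVVFLIAVFFAENKKEDPNSSGDALIVIFVVLFVLVVLLMVVAFQTDGEAKKK
KAQLLLVLIMIMFILLLIIAVLLVQPNKPEKREEDTKKTNQPQKDKRQSKNTDEPTNEPQ
SDTRSHQTNNGGHDRSTKQRSKGPNQKPQDRNNSKGSSNNEGGDKDAADREQDSDQQGHR
DRQDRQQKEQKETGSPKSKNESSGRGTEPKTKEHTREQGEQKSQTGDTGHAHKTDKKPDD
RPTDEESLLEDSSTSKKEEKDQRH
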
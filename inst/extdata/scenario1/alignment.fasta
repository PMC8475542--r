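>target
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>seq001
MCFDAGDVRMVNAAFISESPMMAAAAACMGNHAWRAAALPLCPKAWAARYDFFAWDRFIK
>seq002
RWWAVGIHTTQHAANRPIQTKQAAAAANSAIHALEYAAFWRDAAPIAASCGLAKASSITA
>seq003
MNPGLKAPNAAMAARDHPHANTAAACAELILFWMAAACDAWPQGVVAAEPTASWITEAAK
>seq004
CFAAPNLWRAWRACMDWERCCAKAAAARAGEADNRAYAPCFAGMLFAAVFFAQNQPTTCK
>seq005
APMYIQAQMNDFAAEYKSARAGAAAAAQKLCCTEFAAAGANCAKMWAAWAWTPSCMAQST
>seq006
QTAGDFSYEQQGAAMAVAYNMIAASAANGNLAWPLAAACYMWVCQKAEDMKGAAFVHWAF
>seq007
NINNIAMAGWHWAARQMHTPAEAAAAAAMDWEQSANAALHQENNSFAASYHSQQRSYVVA
>seq008
NADQNYSCLCICAALAYACARPAAAAARCACDKIAAAAAKNIHCGAAAGAIHLMAMAIIR
>seq009
RMNSPRPAAYTWSSEKTALKEWAAAAAQALYIHHFAAAWRAAWTRAAAMMRCVAFAFFAP
>seq010
ITAAISSMPMFCAAANSATYIAAAAMAAMNLLGACAAAWDLESQGSAPSSYSMAFCDYSG
>seq011
YGAMEPIYMLAFAAGTPIQACKAAAAARDPIGRFGAAKPDGEAAPSAASNAFFASEARFF
>seq012
MDFAHWFFVAHAAARCIWAFMRAAAAADYEEFRAFAAAPDGPWRIAAAFYNFPSHGAGAA
>seq013
QVAAAAWSQRMADAPAPTECIAAAAAIATCQRHNAAAAIYVCCYAIAAGVYTATGMYAIS
>seq014
CAWEHSWNDNSFAAADLMTSWFAAAAAEALATATGRAAMVFSVTVWHASPPQTDACGEAG
>seq015
TPAAHIMETAQYAAATSCGRWQAAAAAKYNATQFAAAAAAGQDAAYAAFHVTDAVKMAPS
>seq016
PTMFAVGTLANAAWLKAGAGACAAAAVRAFSYEVAAAAHKVAACMEAALETMHVYPARYA
>seq017
DAAIAIHTRSRMAATAAAATAGAAAAKAAHGKAPAAAAIAAFRNFAAAPGMKRCHWFNLW
>seq018
CFQACFAMEQANALYADAFELPAHMAAEHRHKAAMKAAMVACAAGPAAPDETEFAIWTID
>seq019
ATAAAKWANFATLAWQARRLAKAAAAAIKAAAHHYAAAEIIAIWTAAQSAAAGDRAIWTA
>seq020
MPVAAGFPMADAAAAAHASEAFAAAAACAAYCKQMAAAAQNGECIRAAALAQFNGQLAYD
>seq021
KWEYFAQCPPTFAAVAADVNYAAAAGAWAPTLWDPAEAEAHNSTFAAATMEHAAKLWNRQ
>seq022
MHQNARGRQDALAARFLRMAATAAAAAWDQDESAFAAACFVFPQPMAAAWIPHHYAAAPV
>seq023
RPALASAAAKNAGAALHAHVAIRACAAAITVYCKLAAAPYMPCPMWAAPYVHFVISTGAW
>seq024
YPAAQENAWMACAAMIEIDNHTAAAAAQVNAAYACAASAADASPNRAAFTAWAEHKYAAW
>seq025
QATRWSFWGILFAAWYLYSYCCYAAAAVAPHARMRAAALCLWPENRAANKHGMVFQDAAD
>seq026
AKKRTAAAWCCFAAMSGAAKFNAAAAAACGIYLQDAAAASDAEAAEAARSQALHEVDARY
>seq027
GCFQHASLEKIPAAVNGEGAHRAIAAADAQSFAFYAAAYWSGVAAIAALYRAHLTHMGRR
>seq028
WADPCHAKPVWAAAQRCDAMAQAAAAAMWELAGANAAAMITIFRIYAAAGWADICGYACG
>seq029
IAARHIAPGQDGAAWVPDKHIRAAMAAGDKYAAGPAAAKLTHAERRAAKLNACKAQKLIA
>seq030
PEYFFKKTYAAAAAANWKYNEQAAAAIDARDIRFIAAAPAKSSAKFAAHGGAFWAFWANT
>seq031
AGTIARTAWFYIEASFGAAPSDAAAAAHFGSAAAGAAAFIACPHLTAAEGQVAQEGGPCA
>seq032
ATCDPFRMPADYAAAVYVADLEAAAAAKARAKEAYAAANIMAAQAAHATTFAQFHECHSC
>seq033
AIRHVFRACAEAAAAFAAPAGKAAMNAHMANIVWSAAAWPWDFARTAAWGAYFEAPWLIL
>seq034
CMDVWDSRHVGRALWAACYWWYAAAAAMDFKATAIAAAWPELHSWLAAEMFAHMAKIMWN
>seq035
SISECFEACATIAAFEEVFARNAADAAMAAGHEDAAAAANVLQHCLAAAWPPACALAQQG
>seq036
DRDCVDATSGWTAASDDKLKIAAAAAANFVMPINMAAAAVGNCVKQAACCKGIALAACYG
>seq037
MGEPSVYWWTPQAANWPNKVLLAAQAACAEDCYSEAAAALAHEDPAAAVRAEENPGTIAF
>seq038
VEAAENKTLAAGAAAGNKHWVRAAAAAAIIGAYAYAAARYDAVDAKSAPAVCQQCKMHPN
>seq039
NNRYIGASACRAIEETMRLFAAEAAAADPADAAKAAAAYWAGECVSAAHMAENRAMPRAA
>seq040
NAQIAPGECKIAAATMFGSRHNAAAAAVDEDIYFYAAAEWEPAYQFAPNAWKGSQAARDV
>seq041
GTMFAPMDARLPAAKQDLAVQGAAAAAWAHWQPAKAAAMAAIYRIAAAAGELPRMYDMAH
>seq042
TQPGYKYVVMSQAAFSPHHQVLAAAAAGTMKMLVAAAAFFAPVEAHAATAMTGYFAPFYA
>seq043
TCAFTHAQVTLFAAGSNMAAARAAGAATLIGDSGYAAAKCTTDLKPAASAKNMVQTFGMD
>seq044
RAVAIRTAEDEAAAVAWGQMTKAALAAMLRMAYGKLAATNDAAAAEAKISRWAAAAAVQT
>seq045
IHYFSANAKFFVAAKAAYVPVAAADAAERDCDAWIAASKQEHAFFMAAKAFDAADPIVTQ
>seq046
PDAAFVAMACPHAAFAYKANSAAAAAACHDRATYAAAARAYFAEAIAAPNFAAQWWCHDP
>seq047
ADWWEMIPWIGTAAFQWAGLATAAAAAFWEWAATAAIACAAMCKEWAADTKCAGIPLEDR
>seq048
NAKDAACFVWVCAAICQIWAYLAAAAANLDFVACAAAASCIQVGRNAANCRRFSCQSMAF
>seq049
AEDQAYHMAEEDLAADIMIAALAAAAAMPYLICRFAAAAAMHEGAPAAAAAECWALLLSM
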